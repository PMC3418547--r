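# Configuration-driven orchestration of the analysis stages into one
# reproducible run with a consolidated report.

#' Validate a pipeline configuration file
#'
#' Parses a YAML configuration and collects *all* validation problems
#' (missing input files, non-positive geometry thresholds, malformed
#' sections) rather than stopping at the first.  On success returns the
#' validated configuration; on failure raises a condition of class
#' `config_validation_error` whose `errors` field lists every problem.
#'
#' Recognised sections (each optional, at least one stage required):
#' `seed`, `output_dir`; `alignment` (`file`, `labels`,
#' `reference_id`); `structures` (`rf_model`, `ribosome`, `rf_chain`,
#' `insert_residues`, `decoding_center` with chain/residue ids);
#' `geometry` (`hbond_min`, `hbond_max`, `angle_min`, `clash_overlap`);
#' `genomes` (list of GenBank paths).
#'
#' @param path Path to a YAML configuration file.
#' @return Object of class `pipeline_config`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path))
    stop_mitorf(sprintf("config file '%s' does not exist", path),
                "config_validation_error")
  cfg <- yaml::read_yaml(path)
  errs <- character()
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) return(normalizePath(p))
    cand <- file.path(base, p)
    if (file.exists(cand)) return(normalizePath(cand))
    p
  }
  need_file <- function(p, what) {
    if (is.null(p)) { errs <<- c(errs, sprintf("%s: path missing", what)); return(NULL) }
    rp <- resolve(p)
    if (!file.exists(rp))
      errs <<- c(errs, sprintf("%s: file '%s' does not exist", what, p))
    rp
  }

  if (!is.null(cfg$alignment)) {
    cfg$alignment$file <- need_file(cfg$alignment$file, "alignment.file")
    cfg$alignment$labels <- need_file(cfg$alignment$labels, "alignment.labels")
  }
  if (!is.null(cfg$structures)) {
    cfg$structures$rf_model <- need_file(cfg$structures$rf_model,
                                         "structures.rf_model")
    cfg$structures$ribosome <- need_file(cfg$structures$ribosome,
                                         "structures.ribosome")
  }
  if (!is.null(cfg$genomes)) {
    cfg$genomes <- lapply(seq_along(cfg$genomes), function(i)
      need_file(cfg$genomes[[i]], sprintf("genomes[%d]", i)))
  }
  geo <- cfg$geometry %||% list()
  defaults <- list(hbond_min = 2.4, hbond_max = 3.5, angle_min = 120,
                   clash_overlap = 0.4)
  for (nm in names(defaults)) geo[[nm]] <- geo[[nm]] %||% defaults[[nm]]
  for (nm in names(defaults)) {
    if (!is.numeric(geo[[nm]]) || geo[[nm]] <= 0)
      errs <- c(errs, sprintf("geometry.%s: must be a positive number", nm))
  }
  if (is.numeric(geo$hbond_min) && is.numeric(geo$hbond_max) &&
      geo$hbond_min >= geo$hbond_max)
    errs <- c(errs, "geometry: hbond_min must be below hbond_max")
  cfg$geometry <- geo
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.na(cfg$seed)) errs <- c(errs, "seed: not an integer")
  if (is.null(cfg$alignment) && is.null(cfg$structures) &&
      is.null(cfg$genomes))
    errs <- c(errs, "no stage configured (alignment, structures or genomes)")

  if (length(errs) > 0L) {
    stop(structure(class = c("config_validation_error", "mitorf_error",
                             "error", "condition"),
                   list(message = paste0("invalid configuration:\n  ",
                                         paste(errs, collapse = "\n  ")),
                        errors = errs, call = sys.call(-1))))
  }
  cfg$config_path <- normalizePath(path)
  cfg$config_md5 <- unname(tools::md5sum(cfg$config_path))
  structure(cfg, class = "pipeline_config")
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_mitorf(sprintf("stage '%s' failed: %s", stage,
                        conditionMessage(e)), "stage_error")
  })
}

stamped_tsv <- function(df, path, cfg) {
  con <- file(path, "w")
  writeLines(sprintf("# config_md5=%s seed=%d", cfg$config_md5, cfg$seed),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  close(con)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order — discriminating-position
#' detection, insertion detection and reference mapping with a regional
#' divergence report; decoding-center state classification, binding
#' compatibility and the switch-loop interaction inventory; and the
#' mitogenome terminability scan — writing TSV/JSON outputs (each
#' stamped with the configuration checksum and seed) plus a
#' consolidated `report.json`.  Reruns with an identical configuration
#' are byte-identical; progress messages go to the message stream, not
#' into outputs.
#'
#' @param config A [validate_config()] result or a path to a YAML
#'   configuration.
#' @return Invisibly, the consolidated report list.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  out_dir <- cfg$output_dir %||% "mitorf-out"
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  report <- list(config_md5 = cfg$config_md5, seed = cfg$seed,
                 stages = list())

  if (!is.null(cfg$alignment)) {
    report$stages$alignment <- stage_run("alignment", {
      message("stage alignment: ", cfg$alignment$file)
      aln <- read_labeled_alignment(cfg$alignment$file,
                                    cfg$alignment$labels,
                                    reference_id = cfg$alignment$reference_id)
      pos <- detect_discriminating_positions(aln)
      stamped_tsv(as.data.frame(pos),
                  file.path(out_dir, "discriminating_positions.tsv"), cfg)
      ins <- NULL
      if (!is.null(aln$reference_id)) {
        ins <- detect_insertions(aln)
        stamped_tsv(ins, file.path(out_dir, "insertions.tsv"), cfg)
      }
      rep_div <- divergence_report(pos, insertions = ins)
      write_json_file(list(config_md5 = cfg$config_md5, seed = cfg$seed,
                           counts = as.list(rep_div$counts),
                           n_positions = rep_div$n_positions),
                      file.path(out_dir, "divergence_report.json"))
      list(n_positions = nrow(pos),
           n_insertions = if (is.null(ins)) NA_integer_ else nrow(ins),
           counts = as.list(rep_div$counts))
    })
  }

  if (!is.null(cfg$structures)) {
    report$stages$structures <- stage_run("structures", {
      st <- cfg$structures
      message("stage structures: ", st$rf_model, " + ", st$ribosome)
      rf <- read_structure(st$rf_model)
      ribo <- read_structure(st$ribosome)
      dc <- st$decoding_center %||% list()
      spec <- decoding_center_spec(
        chain = dc$chain %||% "A", a1492 = dc$a1492 %||% 1492,
        a1493 = dc$a1493 %||% 1493, h69_chain = dc$h69_chain %||% "B",
        a1914 = dc$a1914 %||% 1914,
        frame = dc$frame %||% "A:1491,1494:*")
      state <- classify_decoding_state(ribo, spec)
      verdict <- binding_compatibility(
        rf, ribo, spec, state = as.character(state),
        overlap_threshold = cfg$geometry$clash_overlap)
      combined <- merge_models(rf, ribo)
      inv <- switch_loop_interactions(
        combined, spec = spec, rf_chain = st$rf_chain %||% "R",
        insert_residues = unlist(st$insert_residues),
        dist_min = cfg$geometry$hbond_min,
        dist_max = cfg$geometry$hbond_max,
        angle_min = cfg$geometry$angle_min)
      stamped_tsv(as.data.frame(inv),
                  file.path(out_dir, "switch_loop.tsv"), cfg)
      write_json_file(list(config_md5 = cfg$config_md5, seed = cfg$seed,
                           state = as.character(state),
                           compatible = verdict$compatible,
                           n_clashes = nrow(verdict$clashes)),
                      file.path(out_dir, "compatibility.json"))
      list(state = as.character(state), compatible = verdict$compatible,
           n_clashes = nrow(verdict$clashes),
           n_switch_loop_bonds = nrow(inv))
    })
  }

  if (!is.null(cfg$genomes)) {
    report$stages$genomes <- stage_run("genomes", {
      verdicts <- list()
      for (gp in cfg$genomes) {
        message("stage genomes: ", gp)
        genome <- read_mitogenome(gp)
        scan <- scan_genome(genome)
        stamped_tsv(scan$calls,
                    file.path(out_dir, sprintf("termination_%s.tsv",
                                               genome$name)), cfg)
        verdicts[[genome$name]] <- list(
          n_genes = scan$n_genes, all_terminable = scan$all_terminable,
          classes = as.list(table(scan$calls$class)))
      }
      write_json_file(c(list(config_md5 = cfg$config_md5, seed = cfg$seed),
                        verdicts),
                      file.path(out_dir, "genome_verdicts.json"))
      verdicts
    })
  }

  write_json_file(report, file.path(out_dir, "report.json"))
  invisible(report)
}
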