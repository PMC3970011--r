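#' Load a pipeline run configuration
#'
#' Reads a JSON run configuration. Recognized top-level keys:
#'
#' * `annotation`, `annotation_dialect`, `snps`, `snp_format`
#'   (`"ucsc"`/`"vcf"`) — input files, or
#' * `simulation` — an object of [simulation_spec()] arguments
#'   (exactly one of the two routes must be present);
#' * `groups` — object mapping group name to either an array of gene
#'   symbols or the path of a one-symbol-per-line file;
#' * `gene_sets` — optional GMT path for the enrichment stage;
#' * `cases` — `"default"`, `"full"`, or an array of
#'   `{anchor, window_length, utr_requirement}` objects;
#' * `test` — `{n_min, n_max, sidedness, background}` with background
#'   `"whole"` (default; the background includes the group) or
#'   `"disjoint"`;
#' * `snp_rich_min` (default 6), `enrichment`
#'   (`{count_threshold, ease_threshold, sig_level}`);
#' * `out_dir`, `seed`.
#'
#' @param path Path to a JSON file.
#' @return The configuration list (class `run_config`).
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "run_config")
}

read_symbol_file <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(toupper(x[nzchar(x) & !startsWith(x, "#")]))
}

resolve_groups <- function(groups) {
  if (is.null(groups) || length(groups) == 0L) return(list())
  stopifnot(!is.null(names(groups)))
  lapply(groups, function(g) {
    if (is.character(g) && length(g) == 1L && file.exists(g)) {
      read_symbol_file(g)
    } else {
      unique(toupper(as.character(g)))
    }
  })
}

resolve_cases <- function(cases) {
  if (is.null(cases) || identical(cases, "default")) return(default_cases())
  if (identical(cases, "full")) return(default_cases(full = TRUE))
  if (is.data.frame(cases)) {
    cases <- lapply(seq_len(nrow(cases)), function(i) as.list(cases[i, ]))
  }
  out <- lapply(cases, function(cs) {
    case_spec(anchor = cs$anchor,
              window_length = cs$window_length %||% 500L,
              utr_requirement = cs$utr_requirement %||% "any")
  })
  names(out) <- vapply(out, case_label, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(config) {
  has_files <- !is.null(config$annotation) || !is.null(config$snps)
  has_sim <- !is.null(config$simulation)
  if (has_files && has_sim) {
    stop("configuration must choose exactly one of input files or a ",
         "simulation spec, not both", call. = FALSE)
  }
  if (!has_sim && (is.null(config$annotation) || is.null(config$snps))) {
    stop("configuration needs either both 'annotation' and 'snps' paths ",
         "or a 'simulation' block", call. = FALSE)
  }
  if (!has_sim) {
    for (p in c(config$annotation, config$snps)) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
  }
  if (!is.null(config$gene_sets) && !file.exists(config$gene_sets)) {
    stop("gene_sets file not found: ", config$gene_sets, call. = FALSE)
  }
  invisible(TRUE)
}

log_progress <- function(...) {
  message("[promvar] ", ...)
}

#' Run the full promoter-variability pipeline
#'
#' Orchestrates ingest (or simulation), transcript filtering, per-case SNP
#' content tables, the SNP-rich subset, group-vs-background threshold
#' sweeps, and (when gene sets are supplied) enrichment of the SNP-rich
#' gene list — writing every result as TSV under `out_dir` plus a
#' `run_manifest.txt` recording the seed, configuration hash and package
#' version. Identical configuration and seed reproduce byte-identical
#' numeric outputs. Progress is logged to standard error; results go only
#' to files and the returned bundle.
#'
#' @param config A `run_config` (from [load_run_config()]) or an
#'   equivalent list.
#' @return Invisibly, a list with `filter_report`, `contents` (per case),
#'   `snp_rich`, `sweeps` (per group per case), `enrichment` (or `NULL`),
#'   and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  out_dir <- config$out_dir %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  files <- character(0)

  groups <- resolve_groups(config$groups)

  if (!is.null(config$simulation)) {
    log_progress("simulating dataset (seed ", seed, ")")
    sim_args <- config$simulation
    if (!is.null(sim_args$group_sizes)) {
      sim_args$group_sizes <- unlist(sim_args$group_sizes)
    }
    sim_args$seed <- seed
    spec <- do.call(simulation_spec, sim_args)
    ann <- simulate_annotation(spec)
    transcripts_raw <- ann$transcripts
    snps_raw <- simulate_snps(ann$transcripts, ann$truth, spec)
    f_ann <- file.path(out_dir, "simulated_annotation.tsv")
    f_snp <- file.path(out_dir, "simulated_snps.tsv")
    write_transcript_table(transcripts_raw, f_ann)
    write_snp_table(snps_raw, f_snp)
    files <- c(files, f_ann, f_snp)
    if (length(groups) == 0L) {
      # groups fall out of the simulation ground truth
      asg <- ann$truth$assignment
      groups <- lapply(
        setdiff(unique(asg$group), "background"),
        function(g) unique(asg$gene_symbol[asg$group == g])
      )
      names(groups) <- setdiff(unique(asg$group), "background")
    }
  } else {
    log_progress("reading annotation: ", config$annotation)
    transcripts_raw <- read_transcript_table(
      config$annotation,
      dialect = config$annotation_dialect %||% "minimal-8col"
    )
    log_progress("reading SNPs: ", config$snps)
    snps_raw <- if (identical(config$snp_format, "vcf")) {
      read_snp_vcf(config$snps)
    } else {
      read_snp_table(config$snps)
    }
  }

  log_progress("filtering transcripts")
  flt <- filter_transcripts(transcripts_raw)
  f_rep <- file.path(out_dir, "filter_report.tsv")
  write_table(as.data.frame(flt$report), f_rep)
  files <- c(files, f_rep)

  snps <- filter_snps(snps_raw)
  log_progress(nrow(snps), " qualifying SNPs of ", nrow(snps_raw))

  cases <- resolve_cases(config$cases)
  contents <- list()
  for (cl in names(cases)) {
    log_progress("SNP contents: ", format(cases[[cl]]))
    tab <- build_content_table(flt$kept, snps, cases[[cl]])
    contents[[cl]] <- tab
    f <- file.path(out_dir, paste0("contents_", cl, ".tsv"))
    write_table(tab, f)
    files <- c(files, f)
  }

  rich_case <- case_spec("TSS", 500L, "any")
  rich_tab <- contents[[case_label(rich_case)]] %||%
    build_content_table(flt$kept, snps, rich_case)
  snp_rich <- snp_rich_subset(rich_tab, config$snp_rich_min %||% 6L)
  f_rich <- file.path(out_dir, "snp_rich.tsv")
  write_table(snp_rich, f_rich)
  files <- c(files, f_rich)
  log_progress(nrow(snp_rich), " SNP-rich transcripts")

  test_cfg <- config$test %||% list()
  n_range <- (test_cfg$n_min %||% 1L):(test_cfg$n_max %||% 20L)
  sidedness <- test_cfg$sidedness %||% "greater"
  disjoint <- identical(test_cfg$background, "disjoint")

  sweeps <- list()
  for (g in names(groups)) {
    members <- groups[[g]]
    sweeps[[g]] <- list()
    for (cl in names(contents)) {
      bg <- contents[[cl]]
      in_group <- toupper(bg$gene_symbol) %in% members
      grp <- bg[in_group, , drop = FALSE]
      if (nrow(grp) == 0L) {
        warning("group '", g, "' matches no transcript under case ", cl,
                call. = FALSE)
        next
      }
      bg_use <- if (disjoint) bg[!in_group, , drop = FALSE] else bg
      attr(grp, "case") <- attr(bg, "case")
      attr(bg_use, "case") <- attr(bg, "case")
      sw <- threshold_sweep(grp, bg_use, n_range = n_range,
                            sidedness = sidedness, group_name = g)
      sweeps[[g]][[cl]] <- sw
      f <- file.path(out_dir, sprintf("sweep_%s_%s.tsv", g, cl))
      write_table(sw, f)
      files <- c(files, f)
    }
  }

  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    log_progress("enrichment of the SNP-rich gene list")
    sets <- read_gene_sets(config$gene_sets)
    e_cfg <- config$enrichment %||% list()
    enrichment <- enrich_gene_list(
      query = unique(snp_rich$gene_symbol),
      sets = sets,
      background = unique(flt$kept$gene_symbol),
      count_threshold = e_cfg$count_threshold %||% 2L,
      ease_threshold = e_cfg$ease_threshold %||% 0.1,
      sig_level = e_cfg$sig_level %||% 0.05
    )
    f_enr <- file.path(out_dir, "enrichment.tsv")
    write_table(enrichment, f_enr)
    files <- c(files, f_enr)
  }

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, null = "null")
  cfg_file <- file.path(out_dir, "run_config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- c(
    sprintf("promvar version: %s", as.character(utils::packageVersion("promvar"))),
    sprintf("R version: %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", seed),
    sprintf("config md5: %s", unname(tools::md5sum(cfg_file))),
    "coordinates: 0-based half-open (UCSC storage convention)",
    "outputs:",
    paste0("  ", basename(c(files, cfg_file)))
  )
  f_man <- file.path(out_dir, "run_manifest.txt")
  writeLines(manifest, f_man)
  files <- c(files, cfg_file, f_man)
  log_progress("done: ", length(files), " files in ", out_dir)

  invisible(list(filter_report = flt$report, contents = contents,
                 snp_rich = snp_rich, sweeps = sweeps,
                 enrichment = enrichment, files = files))
}
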