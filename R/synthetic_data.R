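# Derive n independent substream seeds from one master seed, restoring the
# caller's RNG state. Adding a stage never perturbs earlier stages' draws.
derive_substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Specify a synthetic annotation + SNP dataset
#'
#' The generator emulates the statistical structure the promoter-variability
#' analysis assumes: transcripts scattered over a few chromosomes with
#' random strand, a 5'UTR length distribution mixing a point mass at zero
#' with a geometric positive part, SNPs placed by an independent per-base
#' Bernoulli process at a genome-wide baseline density, and one or more
#' designated gene groups whose upstream windows receive an elevated
#' density.
#'
#' Defaults: 20000 transcripts, one group of 400, baseline density
#' `0.0037` SNPs/base (the genome-wide upstream-region figure of 3.7 SNPs
#' per 1000 bp), group multiplier 1.5 applied inside the 1000 bp upstream
#' of group members' TSSs, zero-length 5'UTR weight 0.05.
#'
#' @param n_chromosomes Number of chromosomes (named `"1"`, `"2"`, ...).
#' @param chromosome_length Length of each chromosome in bases.
#' @param n_transcripts Number of transcripts to place.
#' @param group_sizes Named integer vector: transcripts per designated
#'   group.
#' @param strand_prob Probability a transcript lies on the `+` strand.
#' @param utr5_zero_weight Point-mass weight of a zero-length 5'UTR.
#' @param utr5_mean Mean of the geometric positive 5'UTR part, bases.
#' @param transcript_length_range Two-vector of min/max transcript length.
#' @param baseline_density SNPs per base genome-wide (lambda0).
#' @param group_multiplier Density multiplier rho (>= 0) inside group
#'   members' elevation windows.
#' @param elevation_window Bases upstream of group TSSs receiving the
#'   elevated density (default 1000, so every 500/1000 x TSS/CRS analysis
#'   case sees the enrichment).
#' @param seed Integer master seed; each generation stage uses an
#'   independent substream derived from it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_chromosomes = 4L,
                            chromosome_length = 30000000L,
                            n_transcripts = 20000L,
                            group_sizes = c(group1 = 400L),
                            strand_prob = 0.5,
                            utr5_zero_weight = 0.05,
                            utr5_mean = 170,
                            transcript_length_range = c(1000L, 100000L),
                            baseline_density = 0.0037,
                            group_multiplier = 1.5,
                            elevation_window = 1000L,
                            seed = 1L) {
  spec <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    n_transcripts = as.integer(n_transcripts),
    group_sizes = group_sizes,
    strand_prob = strand_prob,
    utr5_zero_weight = utr5_zero_weight,
    utr5_mean = utr5_mean,
    transcript_length_range = as.integer(transcript_length_range),
    baseline_density = baseline_density,
    group_multiplier = group_multiplier,
    elevation_window = as.integer(elevation_window),
    seed = as.integer(seed)
  )
  if (spec$n_chromosomes < 1L || spec$chromosome_length < 1L ||
      spec$n_transcripts < 1L) {
    stop("counts must be positive", call. = FALSE)
  }
  if (is.null(names(spec$group_sizes)) || any(spec$group_sizes < 1L)) {
    stop("group_sizes must be a named vector of positive counts",
         call. = FALSE)
  }
  if (sum(spec$group_sizes) > spec$n_transcripts) {
    stop("group sizes exceed n_transcripts", call. = FALSE)
  }
  if (spec$strand_prob < 0 || spec$strand_prob > 1 ||
      spec$utr5_zero_weight < 0 || spec$utr5_zero_weight > 1) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (spec$baseline_density < 0 || spec$group_multiplier < 0 ||
      spec$baseline_density * max(1, spec$group_multiplier) > 1) {
    stop("need 0 <= baseline_density * group_multiplier <= 1", call. = FALSE)
  }
  if (length(spec$transcript_length_range) != 2L ||
      spec$transcript_length_range[1] < 2L ||
      diff(spec$transcript_length_range) < 0L) {
    stop("transcript_length_range must be an increasing pair >= 2",
         call. = FALSE)
  }
  structure(spec, class = "simulation_spec")
}

#' Generate a synthetic transcript catalog
#'
#' Places `n_transcripts` transcripts uniformly (overlap allowed) on the
#' spec's chromosomes, draws strand and 5'UTR length, derives CDS bounds
#' (no 3'UTR is modelled; it plays no role upstream), assigns the
#' designated groups, and returns the ground truth needed for
#' parameter-recovery tests. Deterministic given `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `transcripts` (a transcript table, accessions
#'   `NM_SIM000001`...) and `truth` (class `ground_truth`: `assignment`
#'   data frame with `accession`, `gene_symbol`, `group`,
#'   `lambda_upstream`; plus `spec` and `seed`).
#' @export
simulate_annotation <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$transcript_length_range[2] >= spec$chromosome_length) {
    stop("transcripts cannot fit: increase chromosome_length above ",
         spec$transcript_length_range[2], " or shorten transcripts",
         call. = FALSE)
  }
  seeds <- derive_substream_seeds(spec$seed, 2L)
  set.seed(seeds[1])
  n <- spec$n_transcripts
  L <- spec$chromosome_length
  chrom <- as.character(sample.int(spec$n_chromosomes, n, replace = TRUE))
  tlen <- floor(runif(n, spec$transcript_length_range[1],
                      spec$transcript_length_range[2] + 1))
  tx_start <- floor(runif(n, 0, L - tlen + 1))
  tx_end <- tx_start + tlen
  strand <- ifelse(runif(n) < spec$strand_prob, "+", "-")
  utr <- ifelse(runif(n) < spec$utr5_zero_weight, 0,
                1 + stats::rgeom(n, 1 / spec$utr5_mean))
  utr <- pmin(utr, tlen - 1)  # keep the CDS non-empty
  cds_start <- ifelse(strand == "+", tx_start + utr, tx_start)
  cds_end <- ifelse(strand == "+", tx_end, tx_end - utr)

  transcripts <- data.frame(
    accession = sprintf("NM_SIM%06d", seq_len(n)),
    gene_symbol = sprintf("GSIM%06d", seq_len(n)),
    chrom = chrom, strand = strand,
    tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    stringsAsFactors = FALSE
  )

  group <- rep("background", n)
  member_idx <- sample.int(n, sum(spec$group_sizes))
  offset <- 0L
  for (g in names(spec$group_sizes)) {
    sz <- spec$group_sizes[[g]]
    group[member_idx[(offset + 1L):(offset + sz)]] <- g
    offset <- offset + sz
  }
  truth <- structure(list(
    assignment = data.frame(
      accession = transcripts$accession,
      gene_symbol = transcripts$gene_symbol,
      group = group,
      lambda_upstream = spec$baseline_density *
        ifelse(group == "background", 1, spec$group_multiplier),
      stringsAsFactors = FALSE
    ),
    spec = spec,
    seed = spec$seed
  ), class = "ground_truth")

  list(transcripts = transcripts, truth = truth)
}

# Merge possibly overlapping [start, end) intervals into a disjoint sorted
# union.
interval_union <- function(start, end) {
  if (length(start) == 0L) {
    return(list(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  out_s <- start[1]
  out_e <- end[1]
  j <- 1L
  for (i in seq_along(start)[-1]) {
    if (start[i] <= out_e[j]) {
      out_e[j] <- max(out_e[j], end[i])
    } else {
      j <- j + 1L
      out_s[j] <- start[i]
      out_e[j] <- end[i]
    }
  }
  list(start = out_s, end = out_e)
}

in_intervals <- function(pos, intervals) {
  if (length(intervals$start) == 0L) return(rep(FALSE, length(pos)))
  idx <- findInterval(pos, intervals$start)
  idx > 0L & pos < intervals$end[pmax(idx, 1L)]
}

#' Generate synthetic SNPs for a simulated catalog
#'
#' Places SNPs by an independent per-base Bernoulli process: rate
#' `baseline_density` genome-wide, replaced by `baseline_density *
#' group_multiplier` inside the union of group members' elevation windows
#' (`elevation_window` bases upstream of each group TSS, strand-aware,
#' clipped to the chromosome). Implemented equivalently as a binomial draw
#' of the SNP count followed by uniform sampling of distinct positions.
#' All records are class `"single"` with validation flag
#' `"by-1000genomes"`. Deterministic given `spec$seed` (an independent
#' substream from the one used by [simulate_annotation()]).
#'
#' @param transcripts Transcript table from [simulate_annotation()].
#' @param truth Matching `ground_truth` object.
#' @param spec The same [simulation_spec()].
#' @return A SNP table sorted by (chrom, pos), as from [read_snp_table()].
#' @export
simulate_snps <- function(transcripts, truth, spec) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(truth, "ground_truth"))
  seeds <- derive_substream_seeds(spec$seed, 2L)
  set.seed(seeds[2])
  L <- spec$chromosome_length
  lam0 <- spec$baseline_density
  rho <- spec$group_multiplier

  members <- truth$assignment$group != "background"
  elev <- upstream_window(
    transcripts[members, , drop = FALSE],
    case_spec("TSS", spec$elevation_window, "any")
  )
  elev$end <- pmin(elev$end, L)  # windows past a minus-strand telomere

  chroms <- as.character(seq_len(spec$n_chromosomes))
  pieces <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    k0 <- stats::rbinom(1L, L, lam0)
    pos <- if (k0 > 0L) sample.int(L, k0) - 1L else integer(0)
    sel <- elev$chrom == ch
    if (any(sel) && rho != 1) {
      u <- interval_union(elev$start[sel], elev$end[sel])
      widths <- u$end - u$start
      U <- sum(widths)
      pos <- pos[!in_intervals(pos, u)]
      k1 <- stats::rbinom(1L, U, min(1, lam0 * rho))
      if (k1 > 0L) {
        offs <- sample.int(U, k1) - 1L
        bounds <- cumsum(c(0L, widths))  # bounds[i] <= offset < bounds[i+1]
        iv <- findInterval(offs, bounds)
        elevated <- u$start[iv] + (offs - bounds[iv])
        pos <- c(pos, elevated)
      }
    }
    pos <- sort(pos)
    pieces[[ci]] <- data.frame(chrom = rep(ch, length(pos)),
                               pos = as.integer(pos),
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  if (nrow(out) == 0L) {
    out <- empty_snp_table()
    attr(out, "parse_report") <- new_parse_report()
    attr(out, "duplicates_collapsed") <- 0L
    return(out)
  }
  out$rsid <- sprintf("rsSIM%09d", seq_len(nrow(out)))
  out$variant_class <- rep("single", nrow(out))
  out$validation_flags <- rep("by-1000genomes", nrow(out))
  rownames(out) <- NULL
  attr(out, "parse_report") <- new_parse_report()
  attr(out, "duplicates_collapsed") <- 0L
  out
}

#' Write a transcript table in the minimal 8-column dialect
#'
#' The inverse of `read_transcript_table(dialect = "minimal-8col")`;
#' chromosome names are written with the `"chr"` prefix restored.
#'
#' @param transcripts A transcript table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_transcript_table <- function(transcripts, path) {
  df <- transcripts
  df$chrom <- paste0("chr", normalize_chrom(df$chrom))
  data.table::fwrite(df[, transcript_cols], path, sep = "\t",
                     quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a SNP table in the UCSC 6-column dialect
#'
#' The inverse of [read_snp_table()]: chrom (with `"chr"` restored),
#' chromStart, chromEnd (`pos + 1` for class `"single"`), rsid, class,
#' validation flags.
#'
#' @param snps A SNP table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snp_table <- function(snps, path) {
  df <- data.frame(
    chrom = paste0("chr", normalize_chrom(snps$chrom)),
    chromStart = snps$pos,
    chromEnd = snps$pos + 1L,
    rsid = snps$rsid,
    class = snps$variant_class,
    valid = snps$validation_flags,
    stringsAsFactors = FALSE
  )
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

fixture_refgene_lines <- function() {
  c(
    "NM_000001\tALPHA\tchr1\t+\t10000\t12000\t10200\t11800",
    "NM_000004\tALPHAB\tchr1\t+\t10000\t13000\t10500\t12800",
    "NM_000002\tBETA\tchr1\t-\t20000\t22000\t20200\t21800",
    "NM_000003\tGAMMA\tchr1\t+\t300\t1500\t300\t1400",
    "NM_000005\tDELTA\tchr2\t+\t50000\t55000\t50100\t54000",
    "NM_000006\tEPSILON\tchr2\t-\t60000\t64000\t60500\t63500",
    "NM_000007\tZETA\tchr2\t+\t70000\t72000\t70000\t71500",
    "NM_000008\tETA\tchr1\t+\t30000\t31000\t30100\t30900",
    "NM_000009\tTHETA\tchr2\t-\t80000\t82000\t80200\t81000",
    "XM_000010\tIOTA\tchr1\t+\t40000\t42000\t40100\t41900",
    "NM_000011\tKAPPA\tchrM\t+\t100\t1000\t200\t900",
    "NM_000012\tLAMBDA\tchr2\t-\t90000\t92000\t90100\t91500"
  )
}

fixture_snp_lines <- function() {
  c(
    "chr1\t50\t51\trs1001\tsingle\tby-cluster,by-1000genomes",
    "chr1\t299\t300\trs1002\tsingle\tby-1000genomes",
    "chr1\t300\t301\trs1003\tsingle\tby-1000genomes",
    "chr1\t9400\t9401\trs1004\tsingle\tby-1000genomes",
    "chr1\t9600\t9601\trs1005\tsingle\tby-1000genomes",
    "chr1\t9800\t9801\trs1006\tsingle\tby-1000genomes",
    "chr1\t9800\t9801\trs1006\tsingle\tby-1000genomes",
    "chr1\t9850\t9853\trs1007\tdeletion\tby-1000genomes",
    "chr1\t9860\t9861\trs1008\tsingle\tby-frequency,by-cluster",
    "chr1\t9999\t10000\trs1009\tsingle\tby-1000genomes",
    "chr1\t10000\t10001\trs1010\tsingle\tby-1000genomes",
    "chr1\t10100\t10101\trs1011\tsingle\tby-1000genomes",
    "chr1\t21900\t21901\trs1012\tsingle\tby-1000genomes",
    "chr1\t22000\t22001\trs1013\tsingle\tBy-1000Genomes",
    "chr1\t22400\t22401\trs1014\tsingle\tby-1000genomes",
    "chr1\t22900\t22901\trs1015\tsingle\tby-1000genomes",
    "chr1\t29550\t29551\trs1016\tsingle\tby-1000genomes",
    "chr1\t29700\t29701\trs1017\tsingle\tby-1000genomes",
    "chr2\t10\t11\trs2001\tsingle\tby-1000genomes",
    "chr2\t49100\t49101\trs2002\tsingle\tby-1000genomes",
    "chr2\t49900\t49901\trs2003\tsingle\tby_1000genomes",
    "chr2\t50050\t50051\trs2004\tsingle\tby-1000genomes",
    "chr2\t63700\t63701\trs2005\tsingle\tby-1000genomes",
    "chr2\t64100\t64101\trs2006\tsingle\tby-1000genomes",
    "chr2\t69400\t69401\trs2007\tsingle\tby-1000genomes",
    "chr2\t69600\t69601\trs2008\tsingle\tby-1000genomes",
    "chr2\t69600\t69601\trs2009\tsingle\tby-1000genomes",
    "chr2\t81200\t81201\trs2010\tsingle\tby-1000genomes",
    "chr2\t82100\t82101\trs2011\tsingle\tby-1000genomes",
    "chr2\t91700\t91701\trs2012\tsingle\tby-1000genomes",
    "chr2\t92300\t92301\trs2013\tsingle\tby-1000genomes"
  )
}

fixture_gmt_lines <- function() {
  c(
    "SMELL\tsensory perception of smell\tALPHA\tBETA\tGAMMA\tDELTA",
    "ANTIGEN\tantigen processing and presentation\tETA\tTHETA\tLAMBDA",
    "HOUSEKEEPING\tcontrol set\tZETA\tEPSILON\tALPHA"
  )
}

# Every expected value below was derived by hand from the fixture lines
# above (window arithmetic on paper), not by running the pipeline.
fixture_manifest <- function() {
  contents <- list(
    utrge0_TSS_500 = list(
      NM_000001 = 3L, NM_000002 = 2L, NM_000003 = 2L, NM_000005 = 1L,
      NM_000006 = 1L, NM_000007 = 2L, NM_000008 = 2L, NM_000009 = 1L,
      NM_000012 = 1L),
    utrge0_TSS_1000 = list(
      NM_000001 = 4L, NM_000002 = 3L, NM_000003 = 2L, NM_000005 = 2L,
      NM_000006 = 1L, NM_000007 = 3L, NM_000008 = 2L, NM_000009 = 1L,
      NM_000012 = 1L),
    utrge0_CRS_500 = list(
      NM_000001 = 4L, NM_000002 = 2L, NM_000003 = 2L, NM_000005 = 2L,
      NM_000006 = 1L, NM_000007 = 2L, NM_000008 = 1L, NM_000009 = 1L,
      NM_000012 = 1L),
    utrgt0_TSS_500 = list(
      NM_000001 = 3L, NM_000002 = 2L, NM_000005 = 1L, NM_000006 = 1L,
      NM_000008 = 2L, NM_000009 = 1L, NM_000012 = 1L),
    utrgt0_CRS_500 = list(
      NM_000001 = 4L, NM_000002 = 2L, NM_000005 = 2L, NM_000006 = 1L,
      NM_000008 = 1L, NM_000009 = 1L, NM_000012 = 1L),
    utrgt0_CRS_1000 = list(
      NM_000001 = 6L, NM_000002 = 3L, NM_000005 = 3L, NM_000006 = 2L,
      NM_000008 = 2L, NM_000009 = 1L, NM_000012 = 2L)
  )
  list(
    transcripts = list(
      n_rows = 12L,
      accessions = c("NM_000001", "NM_000004", "NM_000002", "NM_000003",
                     "NM_000005", "NM_000006", "NM_000007", "NM_000008",
                     "NM_000009", "XM_000010", "NM_000011", "NM_000012")
    ),
    snp_table = list(
      n_file_rows = 31L,
      n_records = 30L,
      per_chrom = list(`1` = 17L, `2` = 13L),
      duplicates_collapsed = 1L,
      n_qualifying = 28L
    ),
    filter_report = list(
      n_input = 12L, removed_accession = 1L, removed_chromosome = 1L,
      removed_noncoding = 0L, removed_duplicate_tss = 1L,
      kept = 9L, kept_utr_positive = 7L, kept_utr_zero = 2L
    ),
    contents = contents,
    effective_length_exceptions = list(NM_000003 = 300L),
    snp_rich = list(
      min_6 = character(0),
      min_2 = c("NM_000001", "NM_000002", "NM_000003", "NM_000007",
                "NM_000008")
    )
  )
}

#' Write the hand-auditable fixture bundle
#'
#' Writes four small plain-text files into `dir`: `tiny_refgene.tsv` (12
#' transcripts on 2 chromosomes covering both strands, a duplicate-TSS
#' pair, an `XM_` accession, a `chrM` record, zero-length 5'UTRs and a
#' window clipped at position 0), `tiny_snps.tsv` (31 rows exercising
#' window boundaries, an exact duplicate, a non-`single` class, a record
#' without the 1000-genomes flag, shared-position rsids and flag-casing
#' variants), `toy_sets.gmt` (3 gene sets) and `tiny_manifest.json` — the
#' hand-computed expected values for every downstream statistic.
#' Regeneration is byte-identical; copies ship under
#' `system.file("extdata", package = "promvar")`.
#'
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the four file paths.
#' @export
make_fixture <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    refgene = file.path(dir, "tiny_refgene.tsv"),
    snps = file.path(dir, "tiny_snps.tsv"),
    gmt = file.path(dir, "toy_sets.gmt"),
    manifest = file.path(dir, "tiny_manifest.json")
  )
  writeLines(fixture_refgene_lines(), paths[["refgene"]])
  writeLines(fixture_snp_lines(), paths[["snps"]])
  writeLines(fixture_gmt_lines(), paths[["gmt"]])
  jsonlite::write_json(fixture_manifest(), paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
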