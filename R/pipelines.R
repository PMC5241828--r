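# End-to-end analyses tying the modules together, with TSV/JSON reporting.
# Every stochastic run requires an explicit seed, echoed (with the full
# configuration and a config hash) into every output header, so re-running
# with the same config and inputs reproduces the outputs byte for byte.

config_hash <- function(config) {
  # polynomial rolling hash of the deparsed config; a provenance echo,
  # not a cryptographic digest. The output location is not part of the
  # analysis, so identical analyses hash identically wherever written.
  config$out_dir <- NULL
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

pkg_version <- function() {
  as.character(utils::packageVersion("nucperi"))
}

report_header <- function(config, seed) {
  c(sprintf("# nucperi %s", pkg_version()),
    sprintf("# seed=%s config_hash=%s", seed, config_hash(config)))
}

write_report_tsv <- function(df, path, config, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(config, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_report_json <- function(x, path, config, seed) {
  x$tool <- list(name = "nucperi", version = pkg_version(),
                 seed = seed, config_hash = config_hash(config))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

resolve_peaks <- function(x, genome, format = "narrowPeak") {
  if (methods::is(x, "GRanges")) return(x)
  read_bed(x, genome, format = format)
}

#' Subtelomeric enrichment analysis of replicate peak sets
#'
#' Chains the interval and enrichment modules: read (or accept) two
#' replicate peak sets, optionally subtract a control peak set, form the
#' replicate-consensus sites, define subtelomeric windows, and test the
#' consensus for subtelomeric enrichment with the permutation and binomial
#' nulls. Writes `consensus.bed`, `enrichment.tsv` and `summary.json` to
#' `out_dir`.
#'
#' @param config List with elements: `genome` (a `Seqinfo`, or
#'   `chrom_sizes` path), `rep1`, `rep2` (paths or `GRanges`), optional
#'   `control`, `format` (BED dialect for paths, default `"narrowPeak"`),
#'   `window_bp` (default 500000), `membership` (default `"midpoint"`),
#'   `n_perm` (default 1000), `seed` (mandatory), `out_dir`.
#' @return Invisibly, a list with `consensus`, `windows`, `enrichment`,
#'   and output paths.
#' @export
run_subtelomere_analysis <- function(config) {
  genome <- if (!is.null(config$genome)) config$genome
            else read_chrom_sizes(config$chrom_sizes)
  fmt <- if (is.null(config$format)) "narrowPeak" else config$format
  rep1 <- resolve_peaks(config$rep1, genome, fmt)
  rep2 <- resolve_peaks(config$rep2, genome, fmt)
  if (length(rep1) == 0L || length(rep2) == 0L)
    stop("empty peak set; nothing to analyse")
  if (!is.null(config$control)) {
    ctrl <- resolve_peaks(config$control, genome, fmt)
    rep1 <- subtract_control(rep1, ctrl)
    rep2 <- subtract_control(rep2, ctrl)
  }
  consensus <- consensus_union(rep1, rep2)
  if (length(consensus) == 0L) stop("no consensus sites between replicates")
  window_bp <- if (is.null(config$window_bp)) 500000L else config$window_bp
  membership <- if (is.null(config$membership)) "midpoint"
                else config$membership
  n_perm <- if (is.null(config$n_perm)) 1000L else config$n_perm
  if (is.null(config$seed)) stop("config$seed is mandatory")
  windows <- subtelomeric_windows(genome, window_bp)
  enr <- permutation_test(consensus, windows, genome, n_perm = n_perm,
                          seed = config$seed, membership = membership)
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    bed <- file.path(config$out_dir, "consensus.bed")
    write_bed(consensus, bed)
    tsv <- file.path(config$out_dir, "enrichment.tsv")
    df <- data.frame(n_obs = enr$n_obs, n_total = enr$n_total,
                     f_obs = enr$f_obs, f_exp = enr$f_exp, fold = enr$fold,
                     p_perm = enr$p_perm, p_binom = enr$p_binom,
                     n_perm = enr$n_perm, window_bp = window_bp,
                     membership = membership, seed = config$seed)
    write_report_tsv(df, tsv, config, config$seed)
    js <- file.path(config$out_dir, "summary.json")
    write_report_json(list(
      analysis = "subtelomere",
      n_rep1 = length(rep1), n_rep2 = length(rep2),
      n_consensus = length(consensus),
      enrichment = df, warnings = list()), js, config, config$seed)
    paths <- c(consensus = bed, enrichment = tsv, summary = js)
  }
  invisible(list(consensus = consensus, windows = windows,
                 enrichment = enr, paths = paths))
}

condition_shell_counts <- function(samples, n_shells) {
  counts <- rep(0L, n_shells); outside <- 0L; rows <- NULL
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    mask <- if (!is.null(s$mask)) s$mask
            else segment_nuclei(s$image, min_area_px = 200L)
    labs <- sort(unique(mask[mask > 0]))
    for (k in labs) {
      part <- shell_partition(mask == k, n_shells)
      asg <- assign_to_shells(s$points, part)
      counts <- counts + asg$counts
      outside <- outside + asg$n_outside
      rows <- rbind(rows, data.frame(sample = i, nucleus = k,
                                     shell = seq_len(n_shells),
                                     count = asg$counts))
    }
  }
  list(counts = counts, outside = outside, rows = rows)
}

#' Radial (shell) positioning analysis of locus spots
#'
#' For each condition, partitions every nucleus mask into equal-area
#' shells, assigns the condition's spot positions to shells, aggregates
#' per-condition shell distributions, and compares the first two
#' conditions per shell (Fisher exact) and overall (chi-square). Writes
#' `shell_counts.tsv` and `summary.json` when `out_dir` is given.
#'
#' @param config List with: `conditions` -- named list (>= 1) of sample
#'   lists, each sample `list(mask = label matrix | image = matrix, points
#'   = (x, y) table)`; `n_shells` (default 5); `seed` (mandatory); optional
#'   `out_dir`.
#' @return Invisibly, a list with per-condition `counts`, `n_outside`,
#'   per-nucleus rows, and the `tests` between the first two conditions.
#' @export
run_position_analysis <- function(config) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  n_shells <- if (is.null(config$n_shells)) 5L else config$n_shells
  conds <- config$conditions
  if (is.null(names(conds))) stop("conditions must be named")
  res <- lapply(conds, condition_shell_counts, n_shells = n_shells)
  tests <- NULL
  if (length(res) >= 2L)
    tests <- shell_distribution_test(res[[1L]]$counts, res[[2L]]$counts)
  rows <- do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]$rows; r$condition <- nm; r
  }))
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(config$out_dir, "shell_counts.tsv")
    write_report_tsv(rows, tsv, config, config$seed)
    js <- file.path(config$out_dir, "summary.json")
    write_report_json(list(
      analysis = "position",
      n_shells = n_shells,
      counts = lapply(res, `[[`, "counts"),
      n_outside = lapply(res, `[[`, "outside"),
      fisher_p = tests$fisher_p, chisq_p = tests$chisq_p),
      js, config, config$seed)
    paths <- c(counts = tsv, summary = js)
  }
  invisible(list(counts = lapply(res, `[[`, "counts"),
                 n_outside = lapply(res, `[[`, "outside"),
                 rows = rows, tests = tests, paths = paths))
}

#' Peripheral-enrichment profile analysis
#'
#' For each condition, segments nuclei (or uses supplied masks), extracts
#' a major-axis line profile per nucleus, computes the peripheral-
#' enrichment ratio, and summarises conditions by their median ratio; two
#' conditions are compared with a Mann-Whitney test (delegated to
#' [stats::wilcox.test]). Nuclei whose plateau fails (median <= 0) are
#' excluded and counted. Writes `profiles.tsv` and `summary.json` when
#' `out_dir` is given.
#'
#' @param config List with: `conditions` -- named list of sample lists,
#'   each sample `list(image, mask = NULL, dna = NULL)` (`dna` is
#'   segmented when `mask` is absent; otherwise `image` itself is);
#'   `edge_fraction` (default 0.25); `background` (default 0); `seed`
#'   (mandatory); optional `out_dir`.
#' @return Invisibly, a list with the per-nucleus data frame, per-condition
#'   medians, `wilcox_p` (when two conditions), and `n_failed`.
#' @export
run_profile_analysis <- function(config) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  edge <- if (is.null(config$edge_fraction)) 0.25 else config$edge_fraction
  bg <- if (is.null(config$background)) 0 else config$background
  conds <- config$conditions
  if (is.null(names(conds))) stop("conditions must be named")
  rows <- NULL; n_failed <- 0L
  for (nm in names(conds)) {
    for (i in seq_along(conds[[nm]])) {
      s <- conds[[nm]][[i]]
      mask <- if (!is.null(s$mask)) s$mask
              else segment_nuclei(if (!is.null(s$dna)) s$dna else s$image,
                                  min_area_px = 200L)
      for (k in sort(unique(mask[mask > 0]))) {
        pe <- tryCatch({
          prof <- line_profile(s$image, mask == k, background = bg)
          peripheral_enrichment(prof, edge_fraction = edge)
        }, error = function(e) NULL)
        if (is.null(pe)) { n_failed <- n_failed + 1L; next }
        rows <- rbind(rows, data.frame(
          condition = nm, sample = i, nucleus = k, max1 = pe$max1,
          max2 = pe$max2, plateau_median = pe$plateau_median,
          ratio = pe$ratio))
      }
    }
  }
  if (is.null(rows)) stop("no usable nuclei in any condition")
  med <- tapply(rows$ratio, rows$condition, stats::median)
  wp <- NA_real_
  cn <- unique(rows$condition)
  if (length(cn) == 2L) {
    g1 <- rows$ratio[rows$condition == cn[1L]]
    g2 <- rows$ratio[rows$condition == cn[2L]]
    if (length(g1) >= 2L && length(g2) >= 2L)
      wp <- stats::wilcox.test(g1, g2)$p.value
  }
  paths <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(config$out_dir, "profiles.tsv")
    write_report_tsv(rows, tsv, config, config$seed)
    js <- file.path(config$out_dir, "summary.json")
    write_report_json(list(
      analysis = "profile", medians = as.list(med),
      wilcox_p = wp, n_nuclei = nrow(rows), n_failed = n_failed),
      js, config, config$seed)
    paths <- c(profiles = tsv, summary = js)
  }
  invisible(list(rows = rows, medians = med, wilcox_p = wp,
                 n_failed = n_failed, paths = paths))
}
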