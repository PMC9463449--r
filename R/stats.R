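check_strat <- function(tab) {
  if (length(dim(tab)) != 3 || any(dim(tab)[1:2] != 2)) {
    stop("expected a 2 x 2 x K stratified table")
  }
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  tab
}

strat_cells <- function(tab, k) {
  c(a = as.numeric(tab[1, 1, k]), b = as.numeric(tab[1, 2, k]),
    c = as.numeric(tab[2, 1, k]), d = as.numeric(tab[2, 2, k]))
}

#' Cochran-Mantel-Haenszel test on a replicate-stratified 2x2xK table
#'
#' Tests association between class membership and sample across K
#' independent strata (experimental replicates) without continuity
#' correction: chi-square = (sum(a_k - E_k))^2 / sum(V_k) with E_k, V_k
#' the hypergeometric mean and variance of the top-left cell, 1 df.
#' Strata with a zero margin carry no information and are dropped with a
#' warning.
#'
#' @param tab 2 x 2 x K array (rows: in/not in class; columns: comparison/
#'   reference; see [stratified_table()]).
#' @param correct Apply the 0.5 continuity correction (default FALSE).
#' @return List (class `htest`): `statistic`, `parameter` (df), `p.value`.
#' @export
cmh_test <- function(tab, correct = FALSE) {
  tab <- check_strat(tab)
  K <- dim(tab)[3]
  keep <- vapply(seq_len(K), function(k) {
    all(rowSums(tab[, , k]) > 0) && all(colSums(tab[, , k]) > 0)
  }, TRUE)
  if (!all(keep)) {
    warning(sum(!keep), " stratum/strata with a zero margin dropped")
    tab <- tab[, , keep, drop = FALSE]
    if (dim(tab)[3] == 0) stop("no informative strata remain")
  }
  num <- 0; den <- 0
  for (k in seq_len(dim(tab)[3])) {
    x <- strat_cells(tab, k)
    Tk <- sum(x)
    E <- (x["a"] + x["b"]) * (x["a"] + x["c"]) / Tk
    V <- (x["a"] + x["b"]) * (x["c"] + x["d"]) *
      (x["a"] + x["c"]) * (x["b"] + x["d"]) / (Tk^2 * (Tk - 1))
    num <- num + (x["a"] - E)
    den <- den + V
  }
  dev <- abs(num) - if (correct) 0.5 else 0
  stat <- unname(max(dev, 0)^2 / den)
  structure(list(statistic = c(chisq = stat), parameter = c(df = 1),
                 p.value = pchisq(stat, 1, lower.tail = FALSE),
                 method = "Cochran-Mantel-Haenszel chi-squared test",
                 data.name = deparse(substitute(tab))),
            class = "htest")
}

# Mantel-Haenszel common odds ratio
mh_common_or <- function(tab) {
  num <- 0; den <- 0
  for (k in seq_len(dim(tab)[3])) {
    x <- strat_cells(tab, k)
    Tk <- sum(x)
    num <- num + x["a"] * x["d"] / Tk
    den <- den + x["b"] * x["c"] / Tk
  }
  unname(num / den)
}

# expected top-left cell of one 2x2 under a given odds ratio: solves
# a(d')/( (r1-a)(c1-a) ) = or on the feasible open interval (monotone)
bd_expected_a <- function(r1, c1, Tk, or) {
  lo <- max(0, r1 + c1 - Tk); hi <- min(r1, c1)
  f <- function(a) a * (Tk - r1 - c1 + a) - or * (r1 - a) * (c1 - a)
  eps <- (hi - lo) * 1e-12
  uniroot(f, c(lo + eps, hi - eps), tol = 1e-12)$root
}

#' Breslow-Day test of odds-ratio homogeneity across strata
#'
#' Tests whether the class-by-sample odds ratio is the same in every
#' replicate stratum: expected top-left cells are computed under the
#' Mantel-Haenszel common odds ratio and compared by chi-square with K - 1
#' df. A non-significant p indicates a homogeneous effect across
#' replicates. The Tarone adjustment is available behind a flag (default
#' off).
#'
#' @param tab 2 x 2 x K array, K >= 2.
#' @param tarone Apply Tarone's correction term (default FALSE).
#' @return `htest` list.
#' @export
breslow_day <- function(tab, tarone = FALSE) {
  tab <- check_strat(tab)
  K <- dim(tab)[3]
  if (K < 2) stop("homogeneity is undefined for a single stratum")
  or <- mh_common_or(tab)
  stat <- 0; dev_sum <- 0; var_sum <- 0
  for (k in seq_len(K)) {
    x <- strat_cells(tab, k)
    Tk <- sum(x)
    at <- bd_expected_a(x["a"] + x["b"], x["a"] + x["c"], Tk, or)
    v <- 1 / (1 / at + 1 / (x["a"] + x["b"] - at) +
                1 / (x["a"] + x["c"] - at) +
                1 / (Tk - (x["a"] + x["b"]) - (x["a"] + x["c"]) + at))
    stat <- stat + (x["a"] - at)^2 / v
    dev_sum <- dev_sum + (x["a"] - at)
    var_sum <- var_sum + v
  }
  if (tarone) stat <- stat - dev_sum^2 / var_sum
  stat <- unname(stat)
  structure(list(statistic = c(chisq = stat), parameter = c(df = K - 1),
                 p.value = pchisq(stat, K - 1, lower.tail = FALSE),
                 estimate = c(common.OR = or),
                 method = paste0("Breslow-Day test",
                                 if (tarone) " (Tarone corrected)"),
                 data.name = deparse(substitute(tab))),
            class = "htest")
}

#' Woolf test of odds-ratio homogeneity across strata
#'
#' Inverse-variance comparison of per-stratum log odds ratios after adding
#' 0.5 to every cell (Haldane-Anscombe correction, so zero cells stay
#' finite): chi-square = sum w_k (lnOR_k - lnOR_pooled)^2 with
#' w_k = 1/Var(lnOR_k), K - 1 df.
#'
#' @param tab 2 x 2 x K array, K >= 2.
#' @return `htest` list.
#' @export
woolf_test <- function(tab) {
  tab <- check_strat(tab)
  K <- dim(tab)[3]
  if (K < 2) stop("homogeneity is undefined for a single stratum")
  lor <- numeric(K); w <- numeric(K)
  for (k in seq_len(K)) {
    x <- strat_cells(tab, k) + 0.5
    lor[k] <- log(x["a"] * x["d"] / (x["b"] * x["c"]))
    w[k] <- 1 / sum(1 / x)
  }
  pooled <- sum(w * lor) / sum(w)
  stat <- sum(w * (lor - pooled)^2)
  structure(list(statistic = c(chisq = stat), parameter = c(df = K - 1),
                 p.value = pchisq(stat, K - 1, lower.tail = FALSE),
                 estimate = c(pooled.logOR = pooled),
                 method = "Woolf test of odds-ratio homogeneity",
                 data.name = deparse(substitute(tab))),
            class = "htest")
}

#' Per-interval Student's t-tests of a feature against a reference sample
#'
#' Within each time interval (default 12 h), compares the feature values
#' of every non-reference sample to the reference by a two-sample,
#' two-tailed Student's t-test (pooled variance), then Bonferroni-adjusts
#' over the whole family of (sample x interval) comparisons.
#'
#' @param df Data frame with `sample`, `time_h` and the feature column.
#' @param feature Feature column name.
#' @param reference Reference sample name.
#' @param interval_h Interval width in hours (default 12).
#' @return Tibble: sample, interval_start_h, mean_ref, mean_cmp, t, df, p,
#'   p_adj. Intervals with a degenerate group are skipped with a message.
#' @export
interval_ttests <- function(df, feature, reference, interval_h = 12) {
  stopifnot(all(c("sample", "time_h", feature) %in% names(df)))
  df <- df[!is.na(df[[feature]]), , drop = FALSE]
  df$..iv <- floor(df$time_h / interval_h) * interval_h
  samples <- setdiff(sort(unique(df$sample)), reference)
  rows <- list(); n_skip <- 0L
  for (smp in samples) {
    for (iv in sort(unique(df$..iv))) {
      xr <- df[[feature]][df$sample == reference & df$..iv == iv]
      xc <- df[[feature]][df$sample == smp & df$..iv == iv]
      if (length(xr) < 2 || length(xc) < 2) { n_skip <- n_skip + 1L; next }
      tt <- tryCatch(t.test(xc, xr, var.equal = TRUE),
                     error = function(e) NULL)
      if (is.null(tt)) { n_skip <- n_skip + 1L; next }
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = smp, interval_start_h = iv,
        mean_ref = mean(xr), mean_cmp = mean(xc),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value)
    }
  }
  if (n_skip > 0) message("interval_ttests: ", n_skip,
                          " degenerate comparison(s) skipped")
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) out$p_adj <- pmin(1, out$p * nrow(out))
  out
}

#' Enrichment heatmap table: log2 fold changes with stratified statistics
#'
#' For every class and every non-reference sample: the log2 fold change of
#' the class proportion from the reference (counts pooled across
#' replicates), the CMH association p-value, and an odds-ratio-homogeneity
#' p-value (Woolf by default, Breslow-Day optionally). Both p-value
#' families are Bonferroni-adjusted over all (class x sample) tests in the
#' table. Row (class) and column (sample) orders come from complete-
#' linkage hierarchical clustering of Euclidean distances on the log2FC
#' matrix.
#'
#' @param counts Output of [quantify_classes()] (non-interval form).
#' @param reference Reference sample name.
#' @param homogeneity `"woolf"` (data-driven states / trajectories) or
#'   `"breslow_day"` (user-defined phenotypes).
#' @param tarone Passed to [breslow_day()].
#' @return List: `table` (tibble: class, sample, log2fc, ref_proportion,
#'   cmp_proportion, p_cmh, p_cmh_adj, p_homogeneity, p_homogeneity_adj),
#'   `row_order` (classes), `col_order` (samples).
#' @export
fold_change_table <- function(counts, reference,
                              homogeneity = c("woolf", "breslow_day"),
                              tarone = FALSE) {
  homogeneity <- match.arg(homogeneity)
  classes <- sort(unique(counts$class))
  samples <- setdiff(sort(unique(counts$sample)), reference)
  if (!reference %in% counts$sample) stop("reference sample absent: ", reference)
  rows <- list()
  for (cl in classes) {
    for (smp in samples) {
      tab <- stratified_table(counts, cl, smp, reference)
      pooled_in <- apply(tab[1, , , drop = FALSE], 2, sum)
      pooled_tot <- apply(tab, 2, sum)
      p_cmp <- pooled_in[smp] / pooled_tot[smp]
      p_ref <- pooled_in[reference] / pooled_tot[reference]
      if (p_cmp == 0 && p_ref == 0) {
        message("class ", cl, " absent in both ", smp, " and ", reference,
                "; skipped")
        next
      }
      l2 <- if (p_ref > 0) log2(p_cmp / p_ref) else NA_real_
      if (is.na(l2)) message("class ", cl, ": zero reference proportion, ",
                             "log2FC undefined for ", smp)
      cm <- tryCatch(suppressWarnings(cmh_test(tab)), error = function(e) NULL)
      ho <- if (dim(tab)[3] >= 2) {
        tryCatch(if (homogeneity == "woolf") woolf_test(tab)
                 else breslow_day(tab, tarone), error = function(e) NULL)
      } else NULL
      rows[[length(rows) + 1]] <- tibble::tibble(
        class = cl, sample = smp, log2fc = unname(l2),
        ref_proportion = unname(p_ref), cmp_proportion = unname(p_cmp),
        p_cmh = if (is.null(cm)) NA_real_ else cm$p.value,
        p_homogeneity = if (is.null(ho)) NA_real_ else ho$p.value)
    }
  }
  tabout <- dplyr::bind_rows(rows)
  m <- nrow(tabout)
  tabout$p_cmh_adj <- pmin(1, tabout$p_cmh * m)
  tabout$p_homogeneity_adj <- pmin(1, tabout$p_homogeneity * m)
  fc <- matrix(0, length(classes), length(samples),
               dimnames = list(classes, samples))
  fc[cbind(match(tabout$class, classes), match(tabout$sample, samples))] <-
    ifelse(is.na(tabout$log2fc), 0, tabout$log2fc)
  row_order <- classes
  col_order <- samples
  if (length(classes) >= 3) {
    row_order <- classes[hclust(dist(fc), method = "complete")$order]
  }
  if (length(samples) >= 3) {
    col_order <- samples[hclust(dist(t(fc)), method = "complete")$order]
  }
  list(table = tabout, row_order = row_order, col_order = col_order)
}

#' Normalised object counts over time
#'
#' Object counts per frame for each (sample, replicate), normalised to the
#' count at a reference frame. Series with a zero initial count are
#' omitted with a message.
#'
#' @param records Track table with `sample` and `replicate`.
#' @param reference_frame Frame whose count normalises the series
#'   (default 0).
#' @return Tibble: sample, replicate, frame, time_h, count, normalized.
#' @export
count_curve <- function(records, reference_frame = 0) {
  stopifnot(all(c("sample", "replicate", "frame") %in% names(records)))
  if (!"time_h" %in% names(records)) records$time_h <- records$frame
  grp <- dplyr::summarise(
    dplyr::group_by_at(records, c("sample", "replicate", "frame")),
    count = dplyr::n(), time_h = min(time_h), .groups = "drop")
  out <- list()
  for (key in split(grp, paste(grp$sample, grp$replicate, sep = "\r"))) {
    init <- key$count[key$frame == reference_frame]
    if (length(init) == 0 || init == 0) {
      message("count_curve: no objects at reference frame for sample ",
              key$sample[1], " replicate ", key$replicate[1], "; omitted")
      next
    }
    key$normalized <- key$count / init
    out[[length(out) + 1]] <- key
  }
  dplyr::arrange(dplyr::bind_rows(out), sample, replicate, frame)
}
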