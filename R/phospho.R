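#' Filter a phosphosite table to analysable sites
#'
#' Keeps sites annotated as late-phase and as belonging to exactly one
#' spatial compartment (multi-compartment annotations are `;`-separated),
#' reporting how many sites were dropped for each reason.  Filtering is
#' idempotent.
#'
#' @param table data.frame with at least `compartment`, `class` and
#'   timecourse (`t_*`) columns, as from [generate_phospho_dataset()].
#' @return the kept rows, with attributes `n_dropped_early` and
#'   `n_dropped_multi`.
#' @export
load_filter_sites <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("site table is empty", call. = FALSE)
  need <- c("compartment", "class")
  miss <- setdiff(need, names(table))
  tc <- grep("^t_", names(table), value = TRUE)
  if (length(tc) == 0) miss <- c(miss, "timecourse columns t_*")
  if (length(miss))
    stop("site table is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  is_late <- table$class == "late"
  is_single <- !grepl(";", table$compartment, fixed = TRUE)
  kept <- table[is_late & is_single, , drop = FALSE]
  attr(kept, "n_dropped_early") <- sum(!is_late)
  attr(kept, "n_dropped_multi") <- sum(is_late & !is_single)
  kept
}

#' Per-compartment phosphosite rate-change times
#'
#' Applies [site_change_time()] to each site's timecourse and summarises by
#' compartment (n, mean, s.e.m.), flagging zero-variance groups.  Per-site
#' failures are recorded, not fatal.
#'
#' @param sites filtered site table ([load_filter_sites()]).
#' @param time normalised time grid; defaults to an even grid over the
#'   `t_*` columns.
#' @return object of class `"compartment_timing"`: `sites` (with a
#'   `change_time` column), `summary` (per-compartment data.frame with `n`,
#'   `mean`, `sem`, `zero_variance`), `failures`.
#' @export
compartment_change_times <- function(sites, time = NULL) {
  tc <- grep("^t_", names(sites), value = TRUE)
  time <- time %||% seq(0, 1, length.out = length(tc))
  ct <- rep(NA_real_, nrow(sites))
  fails <- list()
  for (i in seq_len(nrow(sites))) {
    res <- tryCatch(
      site_change_time(as.numeric(sites[i, tc]), time = time),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        site_id = sites$site_id[i] %||% as.character(i),
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else ct[i] <- res
  }
  sites$change_time <- ct
  ok <- !is.na(ct)
  comp <- unique(sites$compartment)
  summ <- do.call(rbind, lapply(comp, function(cp) {
    v <- ct[ok & sites$compartment == cp]
    data.frame(compartment = cp, n = length(v), mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               zero_variance = length(v) > 1 && stats::sd(v) == 0,
               stringsAsFactors = FALSE)
  }))
  structure(list(sites = sites, summary = summ,
                 failures = if (length(fails)) do.call(rbind, fails) else
                   data.frame(site_id = character(0), reason = character(0))),
            class = "compartment_timing")
}

#' @export
print.compartment_timing <- function(x, ...) {
  cat("compartment_timing: per-compartment rate-change times\n")
  print(x$summary, row.names = FALSE)
  if (nrow(x$failures))
    cat(sprintf("  %d site(s) failed change-point estimation\n",
                nrow(x$failures)))
  invisible(x)
}

#' Left-tailed Welch (unequal-variance) two-sample t-test
#'
#' Tests whether group `a` changes earlier than group `b`:
#' `t = (mean_a - mean_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch--Satterthwaite degrees of freedom and `p = P(T_df <= t)`.
#' When both groups have zero variance the statistic is undefined; the
#' degenerate path reports `p = 0` if `mean_a < mean_b`, `p = 1` otherwise,
#' with a warning and `zero_variance = TRUE` (matching how a comparison
#' against a no-variability cohort must be read).
#'
#' @param a,b numeric vectors (each n >= 2).
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `zero_variance`.
#' @examples
#' welch_left_tailed(c(1, 2, 3), c(4, 5, 6))  # t ~ -3.674, df 4, p ~ 0.011
#' @export
welch_left_tailed <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs >= 2 observations", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  na <- length(a); nb <- length(b)
  if (va == 0 && vb == 0) {
    warning("both groups have zero variance; reporting the degenerate comparison of means",
            call. = FALSE)
    return(list(t = NA_real_, df = NA_real_,
                p = if (mean(a) < mean(b)) 0 else 1,
                mean_a = mean(a), mean_b = mean(b), zero_variance = TRUE))
  }
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = stats::pt(t, df),
       mean_a = mean(a), mean_b = mean(b), zero_variance = FALSE)
}

#' Correlation between site sensitivity (IC50) and change timing
#'
#' Pearson correlation of `log10(IC50)` against the estimated change time
#' (dose scales are multiplicative, hence the log), with a rank-based
#' (Spearman) alternative.  Two-sided p value.
#'
#' @param sites site table carrying `ic50` and `change_time` columns (run
#'   [compartment_change_times()] first if needed).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n`, `method`.
#' @export
ic50_timing_correlation <- function(sites, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!all(c("ic50", "change_time") %in% names(sites)))
    stop("sites must carry 'ic50' and 'change_time' columns", call. = FALSE)
  ok <- !is.na(sites$ic50) & !is.na(sites$change_time)
  if (sum(ok) < 5)
    stop("need >= 5 sites with both IC50 and change time", call. = FALSE)
  x <- log10(sites$ic50[ok]); y <- sites$change_time[ok]
  if (stats::sd(x) == 0)
    stop("IC50 values are constant; correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), method = method)
}

#' Compare compartment timing against a reference compartment
#'
#' Runs [welch_left_tailed()] of the reference compartment's change times
#' against every other compartment.
#'
#' @param timing a `"compartment_timing"` object.
#' @param reference reference compartment (tested as the earlier one).
#' @return data.frame with one row per comparison (`t`, `df`, `p`,
#'   `zero_variance`).
#' @export
compare_compartments <- function(timing, reference = "nucleus") {
  stopifnot(inherits(timing, "compartment_timing"))
  s <- timing$sites
  ok <- !is.na(s$change_time)
  ref <- s$change_time[ok & s$compartment == reference]
  others <- setdiff(unique(s$compartment), reference)
  do.call(rbind, lapply(others, function(cp) {
    res <- suppressWarnings(
      welch_left_tailed(ref, s$change_time[ok & s$compartment == cp]))
    data.frame(reference = reference, compartment = cp, t = res$t,
               df = res$df, p = res$p, zero_variance = res$zero_variance,
               stringsAsFactors = FALSE)
  }))
}
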