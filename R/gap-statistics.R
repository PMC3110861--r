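# ---- reference alignments ---------------------------------------------------

#' A two-row reference (structural) alignment
#'
#' Container for a gapped pairwise alignment treated as ground truth, e.g.
#' derived from superposing two structures. Row order is meaningful: the
#' first row is the template.
#'
#' @param row_a,row_b gapped sequences of equal length over the 20 residue
#'   letters plus `-`.
#' @param id_a,id_b optional sequence identifiers.
#' @return object of class `reference_alignment`.
#' @export
reference_alignment <- function(row_a, row_b, id_a = "A", id_b = "B") {
  if (nchar(row_a) != nchar(row_b))
    abort("alignment rows must have equal length")
  ca <- strsplit(row_a, "")[[1]]
  cb <- strsplit(row_b, "")[[1]]
  if (any(ca == "-" & cb == "-"))
    abort("alignment contains a column with two gap symbols")
  structure(list(row_a = row_a, row_b = row_b, id_a = id_a, id_b = id_b,
                 seq_a = gsub("-", "", row_a), seq_b = gsub("-", "", row_b)),
            class = "reference_alignment")
}

#' @export
print.reference_alignment <- function(x, width = 60, ...) {
  cat(sprintf("Reference alignment (%s / %s), %d columns\n",
              x$id_a, x$id_b, nchar(x$row_a)))
  n <- nchar(x$row_a)
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    cat(substr(x$row_a, s, e), "\n")
    cat(substr(x$row_b, s, e), "\n")
    if (e < n) cat("\n")
  }
  invisible(x)
}

# ---- gap accessibility collection ------------------------------------------

#' Residue-wise gap accessibilities of a reference alignment
#'
#' For every column in which one row is a gap, emits the accessibility of
#' the residue in the other row — one value per residue, no averaging (the
#' statistics convention; the penalty uses segment and flank averages
#' instead). A `NULL` track means that row's protein has no structure and
#' its residues contribute nothing.
#'
#' @param aln a [reference_alignment()].
#' @param track_a,track_b accessibility tracks for the ungapped row
#'   sequences (numeric vectors or track tibbles), or `NULL`.
#' @return numeric vector of accessibilities in \[0, 1\].
#' @export
gap_accessibilities <- function(aln, track_a = NULL, track_b = NULL) {
  stopifnot(inherits(aln, "reference_alignment"))
  ia <- row_indices(aln$row_a)
  ib <- row_indices(aln$row_b)
  va <- if (!is.null(track_a)) track_values(track_a)
  vb <- if (!is.null(track_b)) track_values(track_b)
  if (!is.null(va) && length(va) != max(ia))
    abort(sprintf("track_a length (%d) does not match sequence length (%d)",
                  length(va), max(ia)))
  if (!is.null(vb) && length(vb) != max(ib))
    abort(sprintf("track_b length (%d) does not match sequence length (%d)",
                  length(vb), max(ib)))
  out <- numeric(0)
  if (!is.null(va)) out <- c(out, va[ia[ib == 0]])   # template residues vs gap
  if (!is.null(vb)) out <- c(out, vb[ib[ia == 0]])   # target residues vs gap
  out
}

# ---- binned odds ratios -----------------------------------------------------

#' Binned gap odds ratios
#'
#' Bins gap accessibilities and residue accessibilities into `1/w` bins of
#' width `w` over \[0, 1\] (half-open `[lo, hi)`, last bin closed at 1) and
#' computes, per bin i, the gap frequency `g_i = N_i / sum(N)`, the residue
#' frequency `f_i = A_i / sum(A)`, and the odds ratio `g_i / f_i` of finding
#' a gap at that accessibility. Odds are `NA` (flagged) where the bin holds
#' no residues.
#'
#' @param gap_accs accessibilities of residues aligned against gaps
#'   (see [gap_accessibilities()]).
#' @param residue_accs accessibilities of all residues of the dataset
#'   (conventionally from both proteins of each pair).
#' @param w bin width; must divide 1 evenly (default 0.05).
#' @return tibble of class `gap_bin_table` with columns `bin`, `lo`, `hi`,
#'   `mid`, `n_gap`, `n_res`, `g`, `f`, `odds`.
#' @export
bin_gap_odds <- function(gap_accs, residue_accs, w = 0.05) {
  nb <- 1 / w
  if (abs(nb - round(nb)) > 1e-9) abort("bin width must divide 1 evenly")
  nb <- as.integer(round(nb))
  if (length(residue_accs) == 0)
    abort("residue accessibility list is empty: residue frequencies undefined")
  for (v in list(gap_accs, residue_accs))
    if (length(v) && (any(v < 0) || any(v > 1)))
      abort("accessibility values must lie in [0, 1]")
  n_gap <- tabulate(acc_bin(gap_accs, w, nb), nbins = nb)
  n_res <- tabulate(acc_bin(residue_accs, w, nb), nbins = nb)
  g <- if (sum(n_gap) > 0) n_gap / sum(n_gap) else rep(NA_real_, nb)
  f <- n_res / sum(n_res)
  odds <- ifelse(n_res > 0, g / f, NA_real_)
  out <- tibble(bin = seq_len(nb), lo = (seq_len(nb) - 1) * w,
                hi = seq_len(nb) * w, mid = (seq_len(nb) - 0.5) * w,
                n_gap = as.integer(n_gap), n_res = as.integer(n_res),
                g = g, f = f, odds = odds)
  class(out) <- c("gap_bin_table", class(out))
  attr(out, "w") <- w
  out
}

# half-open bins [lo, hi), value 1 falls in the last bin
acc_bin <- function(x, w, nb) {
  b <- floor(x / w) + 1L
  pmin(as.integer(b), nb)
}

# per-pair bin counts; pairs: list of list(alignment=, track_a=, track_b=)
pair_bin_counts <- function(pairs, w = 0.05) {
  nb <- as.integer(round(1 / w))
  purrr::map(pairs, function(p) {
    ga <- gap_accessibilities(p$alignment, p$track_a, p$track_b)
    res <- c(if (!is.null(p$track_a)) track_values(p$track_a),
             if (!is.null(p$track_b)) track_values(p$track_b))
    list(n_gap = tabulate(acc_bin(ga, w, nb), nbins = nb),
         n_res = tabulate(acc_bin(res, w, nb), nbins = nb))
  })
}

#' Pooled gap odds table over a dataset of aligned pairs
#'
#' @param pairs list of `list(alignment = reference_alignment, track_a =,
#'   track_b =)` entries; tracks may be `NULL` per side.
#' @param w bin width.
#' @return a `gap_bin_table` (see [bin_gap_odds()]); counts add bin-wise
#'   over pairs.
#' @export
gap_odds_table <- function(pairs, w = 0.05) {
  cnt <- pair_bin_counts(pairs, w)
  counts_to_table(Reduce(`+`, purrr::map(cnt, "n_gap")),
                  Reduce(`+`, purrr::map(cnt, "n_res")), w)
}

counts_to_table <- function(n_gap, n_res, w) {
  nb <- length(n_gap)
  g <- if (sum(n_gap) > 0) n_gap / sum(n_gap) else rep(NA_real_, nb)
  f <- if (sum(n_res) > 0) n_res / sum(n_res) else rep(NA_real_, nb)
  out <- tibble(bin = seq_len(nb), lo = (seq_len(nb) - 1) * w,
                hi = seq_len(nb) * w, mid = (seq_len(nb) - 0.5) * w,
                n_gap = as.integer(n_gap), n_res = as.integer(n_res),
                g = g, f = f, odds = ifelse(n_res > 0, g / f, NA_real_))
  class(out) <- c("gap_bin_table", class(out))
  attr(out, "w") <- w
  out
}

#' Bootstrap standard deviations of binned gap odds
#'
#' Resamples whole protein pairs with replacement (preserving within-pair
#' correlation), recomputes the pooled odds table for each replicate, and
#' reports the per-bin standard deviation of the odds ratio.
#'
#' @inheritParams gap_odds_table
#' @param B number of bootstrap resamplings (default 1000).
#' @param seed optional integer seed; a fixed seed makes the result
#'   reproducible.
#' @return tibble with columns `bin`, `mid`, `odds_sd` (`NA` where the odds
#'   were undefined in every replicate).
#' @export
bootstrap_odds_sd <- function(pairs, B = 1000, seed = NULL, w = 0.05) {
  stopifnot(B >= 1, length(pairs) >= 1)
  cnt <- pair_bin_counts(pairs, w)
  gm <- do.call(rbind, purrr::map(cnt, "n_gap"))
  rm_ <- do.call(rbind, purrr::map(cnt, "n_res"))
  nb <- ncol(gm)
  with_seed(seed, {
    reps <- matrix(NA_real_, B, nb)
    for (b in seq_len(B)) {
      idx <- sample.int(length(pairs), replace = TRUE)
      n_gap <- colSums(gm[idx, , drop = FALSE])
      n_res <- colSums(rm_[idx, , drop = FALSE])
      g <- if (sum(n_gap) > 0) n_gap / sum(n_gap) else rep(NA_real_, nb)
      f <- n_res / sum(n_res)
      reps[b, ] <- ifelse(n_res > 0, g / f, NA_real_)
    }
    tibble(bin = seq_len(nb), mid = (seq_len(nb) - 0.5) * w,
           odds_sd = apply(reps, 2, function(v) {
             v <- v[!is.na(v)]
             if (length(v) < 2) NA_real_ else sd(v)
           }))
  })
}

# ---- regression -------------------------------------------------------------

#' Regress binned gap odds on accessibility
#'
#' Least-squares fit of the odds ratio (linear form) or of its natural
#' logarithm (log-linear form) on bin midpoints, over occupied bins.
#' The residual error is the root-mean-square residual in the fitted space
#' (odds for linear, ln odds for log-linear).
#'
#' @param bt a `gap_bin_table`.
#' @param form `"log-linear"` (default) or `"linear"`.
#' @return object of class `odds_fit` with `slope`, `intercept`, `rmse`,
#'   `form`, `n_bins` and the underlying `lm` fit.
#' @export
fit_odds_regression <- function(bt, form = c("log-linear", "linear")) {
  form <- match.arg(form)
  stopifnot(inherits(bt, "gap_bin_table"))
  use <- !is.na(bt$odds)
  if (sum(use) < 2) abort("need at least 2 occupied bins")
  if (form == "log-linear" && any(bt$odds[use] == 0)) {
    bad <- bt$bin[use & bt$odds == 0][1]
    abort(sprintf("odds ratio is zero in bin %d: log-linear fit undefined", bad))
  }
  x <- bt$mid[use]
  y <- if (form == "log-linear") log(bt$odds[use]) else bt$odds[use]
  fit <- lm(y ~ x)
  structure(list(form = form,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 rmse = sqrt(mean(residuals(fit)^2)),
                 n_bins = sum(use), fit = fit),
            class = "odds_fit")
}

#' @export
print.odds_fit <- function(x, ...) {
  lhs <- if (x$form == "log-linear") "ln(odds)" else "odds"
  cat(sprintf("%s fit over %d bins: %s = %.4f * acc + %.4f (rms residual %.4f)\n",
              x$form, x$n_bins, lhs, x$slope, x$intercept, x$rmse))
  invisible(x)
}

#' @method tidy odds_fit
#' @export
tidy.odds_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @method glance odds_fit
#' @export
glance.odds_fit <- function(x, ...) {
  tibble(form = x$form, slope = x$slope, intercept = x$intercept,
         rmse = x$rmse, n_bins = x$n_bins)
}

#' @method autoplot gap_bin_table
#' @export
autoplot.gap_bin_table <- function(object, sd = NULL, log_odds = FALSE, ...) {
  df <- dplyr::filter(object, !is.na(.data$odds))
  if (!is.null(sd)) df <- dplyr::left_join(df, sd, by = c("bin", "mid"))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$odds)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "gap accessibility (bin midpoint)",
                  y = "odds ratio g/f")
  if (!is.null(sd))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$odds - .data$odds_sd,
                   ymax = .data$odds + .data$odds_sd), width = 0.01)
  if (log_odds) p <- p + ggplot2::scale_y_log10()
  p
}

#' @method autoplot odds_fit
#' @export
autoplot.odds_fit <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("y", "x")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "gap accessibility (bin midpoint)",
                  y = if (object$form == "log-linear") "ln odds" else "odds")
}
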