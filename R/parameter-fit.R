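# Brute-force grid fitting of the (alpha, beta) gap penalty parameters.

# precompute encoded sequences and reference-pair lookups for one corpus
prepare_corpus <- function(corpus, sm) {
  alph <- rownames(sm)
  purrr::map(corpus, function(entry) {
    stopifnot(inherits(entry$reference, "reference_alignment"))
    acc <- track_values(entry$track)
    template <- entry$template %||% entry$reference$seq_a
    target <- entry$target %||% entry$reference$seq_b
    if (length(acc) != nchar(template))
      abort("track length does not match template length in corpus entry")
    rp <- alignment_pairs(entry$reference)
    refmap <- rep(NA_integer_, nchar(template))
    refmap[rp$template] <- rp$target
    list(ea = aa_encode(template, alph, "template sequence"),
         eb = aa_encode(target, alph, "target sequence"),
         acc = acc, refmap = refmap, n_ref = nrow(rp))
  })
}

corpus_q <- function(prep, sm, alpha, beta, ext, max_del_span) {
  correct <- 0; total <- 0
  per_pair <- numeric(length(prep))
  for (k in seq_along(prep)) {
    p <- prep[[k]]
    n <- length(p$acc)
    flank <- if (n == 1) c(p$acc, p$acc) else
      c(p$acc[1], (p$acc[-n] + p$acc[-1]) / 2, p$acc[n])
    open_ins <- beta * exp(-alpha * flank)
    res <- align_acc_cpp(p$ea, p$eb, sm, p$acc, alpha, beta, ext,
                         open_ins, as.integer(max_del_span), FALSE)
    ok <- res$ai > 0 & res$bi > 0
    hit <- sum(p$refmap[res$ai[ok]] == res$bi[ok], na.rm = TRUE)
    correct <- correct + hit
    total <- total + p$n_ref
    per_pair[k] <- hit / p$n_ref
  }
  c(pooled = correct / total, mean = mean(per_pair))
}

#' Fit the gap penalty parameters by grid search
#'
#' Aligns every corpus pair with the accessibility-dependent penalty at
#' each `(alpha, beta)` grid point and scores the result against the
#' reference alignment. A coarse pass over the full grid is followed by a
#' fine pass on a window centred on the coarse optimum. The objective is
#' the pooled Q-score (total correctly aligned pairs over total reference
#' pairs); `objective = "mean"` switches to the mean of per-pair Q-scores.
#' Ties are broken towards the smallest `alpha`, then smallest `beta`.
#'
#' @param corpus list of entries `list(template =, track =, target =,
#'   reference = reference_alignment)`; `template`/`target` default to the
#'   reference's ungapped rows.
#' @param coarse_alpha,coarse_beta coarse grid values (defaults: 1 to 39 in
#'   steps of 1, the published search range).
#' @param fine_step fine-pass grid interval (default 0.1).
#' @param fine_alpha_window,fine_beta_window half-widths of the fine-pass
#'   window around the coarse optimum.
#' @param ext extension penalty (default 1).
#' @param sm substitution matrix.
#' @param objective `"pooled"` (default) or `"mean"`.
#' @param max_del_span deletion span cap passed to the aligner (0 = none).
#' @param verbose print progress per grid stage.
#' @return object of class `gap_fit`: `alpha`, `beta`, `q`, `grid` (tibble
#'   `alpha`, `beta`, `q`, `stage`), plus the coarse optimum.
#' @export
fit_gap_parameters <- function(corpus,
                               coarse_alpha = seq(1, 39, by = 1),
                               coarse_beta = seq(1, 39, by = 1),
                               fine_step = 0.1,
                               fine_alpha_window = 1,
                               fine_beta_window = 2,
                               ext = 1,
                               sm = blosum62_shifted(),
                               objective = c("pooled", "mean"),
                               max_del_span = 0,
                               verbose = FALSE) {
  objective <- match.arg(objective)
  if (length(corpus) == 0) abort("corpus is empty")
  stopifnot(fine_step > 0)
  sm <- ensure_shifted(sm)
  prep <- prepare_corpus(corpus, sm)
  run_stage <- function(alphas, betas, stage) {
    grid <- expand.grid(alpha = alphas, beta = betas, KEEP.OUT.ATTRS = FALSE)
    grid <- grid[order(grid$alpha, grid$beta), , drop = FALSE]
    qs <- vapply(seq_len(nrow(grid)), function(i) {
      corpus_q(prep, sm, grid$alpha[i], grid$beta[i], ext,
               max_del_span)[[objective]]
    }, numeric(1))
    if (verbose)
      message(sprintf("%s pass: %d points, best Q = %.4f", stage,
                      nrow(grid), max(qs)))
    tibble(alpha = grid$alpha, beta = grid$beta, q = qs, stage = stage)
  }
  coarse <- run_stage(coarse_alpha, coarse_beta, "coarse")
  cbest <- coarse[which.max(coarse$q), ] # first max: smallest alpha, beta
  fine_alpha <- seq(max(min(coarse_alpha), cbest$alpha - fine_alpha_window),
                    cbest$alpha + fine_alpha_window, by = fine_step)
  fine_beta <- seq(max(min(coarse_beta), cbest$beta - fine_beta_window),
                   cbest$beta + fine_beta_window, by = fine_step)
  fine <- run_stage(fine_alpha, fine_beta, "fine")
  grid <- dplyr::bind_rows(coarse, fine)
  fbest <- fine[which.max(fine$q), ]
  best <- if (fbest$q >= cbest$q) fbest else cbest
  structure(list(alpha = best$alpha, beta = best$beta, q = best$q,
                 coarse_alpha = cbest$alpha, coarse_beta = cbest$beta,
                 coarse_q = cbest$q, objective = objective, grid = grid),
            class = "gap_fit")
}

#' @export
print.gap_fit <- function(x, ...) {
  cat(sprintf("Gap penalty fit (%s objective): alpha = %.2f, beta = %.2f, Q = %.4f\n",
              x$objective, x$alpha, x$beta, x$q))
  cat(sprintf("  coarse optimum: alpha = %.2f, beta = %.2f, Q = %.4f\n",
              x$coarse_alpha, x$coarse_beta, x$coarse_q))
  invisible(x)
}

#' @method tidy gap_fit
#' @export
tidy.gap_fit <- function(x, ...) x$grid

#' @method glance gap_fit
#' @export
glance.gap_fit <- function(x, ...) {
  tibble(alpha = x$alpha, beta = x$beta, q = x$q,
         coarse_alpha = x$coarse_alpha, coarse_beta = x$coarse_beta,
         coarse_q = x$coarse_q, objective = x$objective)
}

#' @method autoplot gap_fit
#' @export
autoplot.gap_fit <- function(object, stage = "coarse", ...) {
  df <- dplyr::filter(object$grid, .data$stage == !!stage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                   fill = .data$q)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = expression(alpha), y = expression(beta), fill = "Q")
}
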