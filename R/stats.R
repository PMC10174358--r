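# Within-subject inferential statistics: paired t tests and two-factor
# repeated-measures ANOVA with interaction and post-hoc contrasts.

#' Paired t test
#'
#' Classic paired t: `t = mean(d) / (sd(d) / sqrt(n))` on the differences
#' `d = x - y`, with `n - 1` degrees of freedom and a two-sided p value.
#' All-zero differences are flagged as degenerate (t undefined) instead of
#' raising an error, so batch analyses can carry the flag through.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @return An object of class `paired_t`: a list with `t`, `df`, `p`,
#'   `mean_diff`, `n`, and logical `degenerate`.
#' @export
paired_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 2L)
    stop("paired t requires at least two pairs", call. = FALSE)
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) {
    # constant differences: t is 0 (all zero) or +/-Inf; flagged, not an error
    tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    return(structure(list(t = tval, df = n - 1L,
                          p = if (tval == 0) 1 else 0,
                          mean_diff = mean(d), n = n, degenerate = TRUE),
                     class = "paired_t"))
  }
  tval <- mean(d) / (s / sqrt(n))
  structure(list(t = tval, df = n - 1L,
                 p = 2 * stats::pt(-abs(tval), df = n - 1L),
                 mean_diff = mean(d), n = n, degenerate = FALSE),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("Paired t: degenerate (all differences zero), n = %d\n",
                x$n))
  else
    cat(sprintf("Paired t: t(%d) = %.4g, p = %.4g, mean diff = %.4g\n",
                x$df, x$t, x$p, x$mean_diff))
  invisible(x)
}

#' Two-factor repeated-measures ANOVA
#'
#' Fully within-subject two-way ANOVA with one observation per subject and
#' cell. Sums of squares are partitioned into subject, A, A x subject, B,
#' B x subject, A x B and A x B x subject components; each effect's F uses
#' its own effect-by-subject interaction as the error term. No sphericity
#' correction is applied.
#'
#' @param data Data frame (e.g. an [n400_table()] aggregated to one value
#'   per subject and cell).
#' @param within Character vector naming the two within-subject factor
#'   columns, `c(A, B)`.
#' @param dv Name of the dependent-variable column (default `"value"`).
#' @param subject Name of the subject-identifier column.
#' @return An object of class `rm_anova`: a list with `table` (data frame
#'   of effect, df1, df2, SS, MS, F, p), `cell_means`, `marginal_means`,
#'   `grand_mean`, `n_subjects` and `ss_total`. Effects whose error sum of
#'   squares is zero get `F = Inf` and are flagged in a `degenerate`
#'   column.
#' @export
rm_anova <- function(data, within, dv = "value", subject = "subject") {
  stopifnot(is.data.frame(data), length(within) == 2L,
            all(c(within, dv, subject) %in% names(data)))
  A <- factor(data[[within[[1L]]]])
  B <- factor(data[[within[[2L]]]])
  S <- factor(data[[subject]])
  y <- data[[dv]]
  a <- nlevels(A); b <- nlevels(B); n <- nlevels(S)
  if (a < 2L || b < 2L)
    stop("each within factor needs at least two levels", call. = FALSE)
  if (n < 2L)
    stop("repeated-measures ANOVA needs at least two subjects",
         call. = FALSE)
  counts <- table(S, A, B)
  if (any(counts != 1L)) {
    bad <- which(counts != 1L, arr.ind = TRUE)[1L, ]
    stop(sprintf(paste0("design must have exactly one value per subject ",
                        "and cell; subject '%s', cell (%s, %s) has %d"),
                 dimnames(counts)[[1L]][bad[[1L]]],
                 dimnames(counts)[[2L]][bad[[2L]]],
                 dimnames(counts)[[3L]][bad[[3L]]],
                 counts[bad[[1L]], bad[[2L]], bad[[3L]]]), call. = FALSE)
  }
  gm <- mean(y)
  m_s  <- tapply(y, S, mean)
  m_a  <- tapply(y, A, mean)
  m_b  <- tapply(y, B, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_as <- tapply(y, list(A, S), mean)
  m_bs <- tapply(y, list(B, S), mean)
  ss_total <- sum((y - gm)^2)
  ss_s <- a * b * sum((m_s - gm)^2)
  ss_a <- n * b * sum((m_a - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, "+") + gm)^2)
  ss_as <- b * sum((m_as - outer(m_a, m_s, "+") + gm)^2)
  ss_bs <- a * sum((m_bs - outer(m_b, m_s, "+") + gm)^2)
  ss_abs <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
  ss_abs <- max(ss_abs, 0)
  eff <- data.frame(
    effect = c(within[[1L]], within[[2L]],
               paste0(within[[1L]], ":", within[[2L]])),
    df1 = c(a - 1L, b - 1L, (a - 1L) * (b - 1L)),
    df2 = c((a - 1L) * (n - 1L), (b - 1L) * (n - 1L),
            (a - 1L) * (b - 1L) * (n - 1L)),
    SS = c(ss_a, ss_b, ss_ab),
    SS_error = c(ss_as, ss_bs, ss_abs),
    stringsAsFactors = FALSE)
  eff$MS <- eff$SS / eff$df1
  ms_err <- eff$SS_error / eff$df2
  eff$degenerate <- ms_err <= 0
  eff$F <- ifelse(eff$degenerate,
                  ifelse(eff$SS > 0, Inf, 0), eff$MS / ms_err)
  eff$p <- ifelse(eff$degenerate, ifelse(eff$SS > 0, 0, 1),
                  stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE))
  structure(list(table = eff,
                 cell_means = m_ab,
                 marginal_means = stats::setNames(
                   list(m_a, m_b), within),
                 grand_mean = gm,
                 n_subjects = n,
                 ss = c(subject = ss_s, A = ss_a, AxS = ss_as, B = ss_b,
                        BxS = ss_bs, AB = ss_ab, ABxS = ss_abs),
                 ss_total = ss_total),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%d subjects)\n", x$n_subjects))
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-20s F(%d, %d) = %.4g, p = %.4g%s\n",
                tab$effect[[i]], tab$df1[[i]], tab$df2[[i]], tab$F[[i]],
                tab$p[[i]],
                if (tab$degenerate[[i]]) " [degenerate error term]" else ""))
  invisible(x)
}

#' Post-hoc pairwise paired t tests
#'
#' For every pair of levels of `within`, runs a paired t across subjects on
#' the per-subject values (averaged over any remaining design columns),
#' optionally within each level of a conditioning factor `by`. Unadjusted
#' p values are reported alongside a Bonferroni-adjusted column.
#'
#' @inheritParams rm_anova
#' @param within Name of the factor whose levels are compared.
#' @param by Optional name of a conditioning factor; contrasts are computed
#'   separately at each of its levels.
#' @return Data frame with columns `by` (if given), `level1`, `level2`,
#'   `t`, `df`, `p`, `p_bonferroni`, `mean1`, `mean2`.
#' @export
posthoc_pairwise <- function(data, within, by = NULL, dv = "value",
                             subject = "subject") {
  stopifnot(is.data.frame(data), within %in% names(data))
  slice_rows <- if (is.null(by)) list(all = rep(TRUE, nrow(data)))
  else {
    lv <- unique(as.character(data[[by]]))
    stats::setNames(lapply(lv, function(l) data[[by]] == l), lv)
  }
  out <- list()
  for (g in names(slice_rows)) {
    d <- data[slice_rows[[g]], , drop = FALSE]
    levs <- unique(as.character(d[[within]]))
    cellmeans <- tapply(d[[dv]], list(d[[subject]],
                                      factor(d[[within]], levels = levs)),
                        mean)
    combs <- utils::combn(levs, 2L)
    for (j in seq_len(ncol(combs))) {
      l1 <- combs[1L, j]; l2 <- combs[2L, j]
      tt <- paired_t(cellmeans[, l1], cellmeans[, l2])
      out[[length(out) + 1L]] <- data.frame(
        by = g, level1 = l1, level2 = l2, t = tt$t, df = tt$df, p = tt$p,
        mean1 = mean(cellmeans[, l1]), mean2 = mean(cellmeans[, l2]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  if (is.null(by)) res$by <- NULL
  res
}
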