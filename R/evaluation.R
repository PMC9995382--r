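drop_greetings <- function(a, b) {
  keep <- a != GREETING_LABEL & b != GREETING_LABEL
  list(a = a[keep], b = b[keep])
}

#' Percent agreement between two label sequences
#'
#' @param a,b Equal-length label vectors (e.g. human coder vs machine).
#'   Positions where either coder used the greeting pseudo-label are
#'   excluded (greetings are outside the eleven-type space).
#' @return Agreement on the 0-100 scale.
#' @export
percent_agreement <- function(a, b) {
  if (length(a) != length(b))
    stop("label sequences must have equal length", call. = FALSE)
  g <- drop_greetings(a, b)
  if (length(g$a) == 0L) stop("no comparable items", call. = FALSE)
  100 * mean(g$a == g$b)
}

#' Cohen's kappa with asymptotic confidence interval
#'
#' Chance-corrected agreement between two coders over the same items:
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` from the
#' product of the marginal label distributions. The confidence interval
#' uses the large-sample Fleiss-Cohen-Everitt standard error. With
#' `collapse = TRUE` both sequences are first coarsened to the
#' recommended / not-recommended categories. Kappa is undefined (reported
#' as `NA`) when both coders used one single shared label.
#'
#' @param a,b Equal-length label vectors of taxonomy labels (greeting
#'   positions are excluded).
#' @param collapse Compare at category level instead of the 11-type level.
#' @param conf_level Confidence level for the interval.
#' @return An object of class `agreement_result`: `n_items`,
#'   `percent_agreement`, `kappa`, `kappa_ci95`, `p_value` (test of
#'   kappa = 0), `label_space`, `expected_agreement`.
#' @export
cohens_kappa <- function(a, b, collapse = FALSE, conf_level = 0.95) {
  if (length(a) != length(b))
    stop("label sequences must have equal length", call. = FALSE)
  g <- drop_greetings(as.character(a), as.character(b))
  a <- g$a; b <- g$b
  if (length(a) == 0L) stop("no comparable items", call. = FALSE)
  if (collapse) {
    a <- category_of(a)
    b <- category_of(b)
  }
  labs <- sort(unique(c(a, b)))
  n <- length(a)
  tab <- table(factor(a, levels = labs), factor(b, levels = labs)) / n
  p_o <- sum(diag(tab))
  p_i <- rowSums(tab); p_j <- colSums(tab)
  p_e <- sum(p_i * p_j)
  if (length(labs) < 2L || p_e >= 1 - 1e-12) {
    return(structure(
      list(n_items = n, percent_agreement = 100 * p_o, kappa = NA_real_,
           kappa_ci95 = c(NA_real_, NA_real_), p_value = NA_real_,
           label_space = labs, expected_agreement = p_e,
           note = "kappa undefined: a single shared label"),
      class = "agreement_result"))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  # Fleiss, Cohen & Everitt (1969) large-sample variance
  A <- sum(diag(tab) * (1 - (p_i + p_j) * (1 - kappa))^2)
  off <- which(row(tab) != col(tab), arr.ind = TRUE)
  B <- (1 - kappa)^2 * sum(tab[off] *
                             (p_j[off[, 1L]] + p_i[off[, 2L]])^2)
  C <- (kappa - p_e * (1 - kappa))^2
  se <- sqrt(max(A + B - C, 0)) / ((1 - p_e) * sqrt(n))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  # null (kappa = 0) SE for the significance test
  se0 <- sqrt(p_e + p_e^2 - sum(p_i * p_j * (p_i + p_j))) /
    ((1 - p_e) * sqrt(n))
  p_value <- 2 * stats::pnorm(-abs(kappa / se0))
  structure(
    list(n_items = n, percent_agreement = 100 * p_o, kappa = kappa,
         kappa_ci95 = c(kappa - z * se, kappa + z * se),
         p_value = p_value, label_space = labs,
         expected_agreement = p_e),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement over %d items (%d labels)\n", x$n_items,
              length(x$label_space)))
  cat(sprintf("  percent agreement: %.1f%% (expected by chance: %.1f%%)\n",
              x$percent_agreement, 100 * x$expected_agreement))
  if (is.na(x$kappa)) {
    cat("  kappa undefined:", x$note, "\n")
  } else {
    cat(sprintf("  Cohen's kappa: %.2f, 95%% CI [%.2f, %.2f], p = %.3g\n",
                x$kappa, x$kappa_ci95[1], x$kappa_ci95[2], x$p_value))
  }
  invisible(x)
}

#' Correlations between question counts and detail counts
#'
#' Pearson correlations, with two-sided p-values, between each question
#' variable (`n_recommended`, `n_not_recommended`, `prop_recommended`) and
#' each detail variable (`n_relevant`, `n_incorrect`) across a batch of
#' interview summaries. Cells with zero variance are reported as missing.
#'
#' @param summaries Data frame of [summarize_interview()] rows (e.g. from
#'   [simulate_batch()]).
#' @return Data frame with columns `question_variable`, `detail_variable`,
#'   `r`, `p_value`, `n`.
#' @export
batch_correlations <- function(summaries) {
  qvars <- c("n_recommended", "n_not_recommended", "prop_recommended")
  dvars <- c("n_relevant", "n_incorrect")
  stopifnot(all(c(qvars, dvars) %in% names(summaries)))
  if (nrow(summaries) < 3L)
    stop("need at least 3 summaries", call. = FALSE)
  rows <- list()
  for (qv in qvars) for (dv in dvars) {
    x <- summaries[[qv]]; y <- summaries[[dv]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        question_variable = qv, detail_variable = dv,
        r = NA_real_, p_value = NA_real_, n = sum(ok))
    } else {
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        question_variable = qv, detail_variable = dv,
        r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
    }
  }
  do.call(rbind, rows)
}
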