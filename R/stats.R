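#' Stay probabilities by previous reward and transition
#'
#' For each consecutive trial pair (t, t+1) with both trials non-missing, the
#' pair counts as a "stay" when the first-stage choice repeats. Pairs are
#' binned by the *previous* trial's outcome (rewarded +, unrewarded -) and
#' transition type (common, rare), giving the four cells pcom+, prar+,
#' pcom-, prar-. Pairs spanning a missing trial are dropped, not bridged.
#'
#' The derived scores follow the factorial logic of the task: the model-free
#' effect is the reward main effect on staying,
#' `(pcom+ + prar+ - pcom- - prar-) / 2`, and the model-based effect the
#' reward-by-transition interaction, `(pcom+ - prar+ - pcom- + prar-) / 2`.
#'
#' @param trials Single-session trial table ([run_session()] columns).
#' @return An object of class `stay_table`: list with the four cell
#'   probabilities (`p_com_plus`, `p_rar_plus`, `p_com_minus`,
#'   `p_rar_minus`), matching pair counts `n_cell`, `mf_effect`, `mb_effect`,
#'   and `flagged` (names of empty cells, whose probabilities are `NA`).
#' @examples
#' tab <- run_session(make_agent(agent_params(omega = 0)), seed = 1)
#' stay_table(tab)
#' @export
stay_table <- function(trials) {
  stopifnot(all(c("choice1", "transition", "reward", "missing") %in%
                  names(trials)))
  if (all(trials$missing)) stop("all trials missing; no stay pairs")
  n <- nrow(trials)
  if (n < 2L) stop("need at least two trials")
  prev <- seq_len(n - 1L); nxt <- prev + 1L
  ok <- !trials$missing[prev] & !trials$missing[nxt]
  stay <- trials$choice1[nxt] == trials$choice1[prev]
  rew <- trials$reward[prev] == 1L
  com <- trials$transition[prev] == "common"

  cell <- function(keep) {
    k <- ok & keep
    c(n = sum(k), p = if (sum(k) > 0) mean(stay[k]) else NA_real_)
  }
  cells <- rbind(com_plus = cell(com & rew), rar_plus = cell(!com & rew),
                 com_minus = cell(com & !rew), rar_minus = cell(!com & !rew))
  p <- cells[, "p"]; ncell <- as.integer(cells[, "n"])
  flagged <- rownames(cells)[ncell == 0L]
  out <- list(p_com_plus = p[["com_plus"]], p_rar_plus = p[["rar_plus"]],
              p_com_minus = p[["com_minus"]], p_rar_minus = p[["rar_minus"]],
              n_cell = stats::setNames(ncell, rownames(cells)),
              flagged = flagged)
  out$mf_effect <- if (length(flagged)) NA_real_ else
    (out$p_com_plus + out$p_rar_plus - out$p_com_minus - out$p_rar_minus) / 2
  out$mb_effect <- if (length(flagged)) NA_real_ else
    (out$p_com_plus - out$p_rar_plus - out$p_com_minus + out$p_rar_minus) / 2
  structure(out, class = "stay_table")
}

#' @export
print.stay_table <- function(x, ...) {
  cat("Stay probabilities (previous reward x previous transition)\n")
  cat(sprintf("  rewarded:   common %.3f  rare %.3f\n",
              x$p_com_plus, x$p_rar_plus))
  cat(sprintf("  unrewarded: common %.3f  rare %.3f\n",
              x$p_com_minus, x$p_rar_minus))
  cat(sprintf("  MF effect %.3f, MB effect %.3f\n", x$mf_effect, x$mb_effect))
  if (length(x$flagged)) cat("  flagged empty cells:",
                             paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Model-free and model-based effect scores
#'
#' Exact arithmetic on the four stay-probability cells; errors on flagged
#' (empty) cells rather than imputing.
#'
#' @param table A [stay_table()].
#' @return Scalar in \[-1, 1\].
#' @export
mf_effect <- function(table) {
  stopifnot(inherits(table, "stay_table"))
  if (length(table$flagged)) stop("empty stay-table cell(s): ",
                                  paste(table$flagged, collapse = ", "))
  (table$p_com_plus + table$p_rar_plus -
      table$p_com_minus - table$p_rar_minus) / 2
}

#' @rdname mf_effect
#' @export
mb_effect <- function(table) {
  stopifnot(inherits(table, "stay_table"))
  if (length(table$flagged)) stop("empty stay-table cell(s): ",
                                  paste(table$flagged, collapse = ", "))
  (table$p_com_plus - table$p_rar_plus -
      table$p_com_minus + table$p_rar_minus) / 2
}

#' Exclude subjects with excessive missing trials
#'
#' A subject is excluded when the missing-trial fraction exceeds the
#' threshold (strictly) in at least one session — "more than 30% missing
#' trials in at least one session".
#'
#' @param trials Cohort trial table (needs subject_id, intervention, missing).
#' @param threshold Missing-fraction threshold (default 0.30).
#' @return List with `trials` (kept rows), `excluded` (subject ids) and `log`
#'   (subject_id, intervention, n_trials, n_missing, frac_missing, excluded).
#' @export
exclusion_filter <- function(trials, threshold = 0.30) {
  agg <- stats::aggregate(missing ~ subject_id + intervention, data = trials,
                          FUN = function(m) c(n = length(m), miss = sum(m)))
  log <- data.frame(subject_id = agg$subject_id,
                    intervention = agg$intervention,
                    n_trials = agg$missing[, "n"],
                    n_missing = agg$missing[, "miss"],
                    stringsAsFactors = FALSE)
  log$frac_missing <- log$n_missing / log$n_trials
  bad_sessions <- log$frac_missing > threshold
  excluded <- sort(unique(log$subject_id[bad_sessions]))
  log$excluded <- log$subject_id %in% excluded
  list(trials = trials[!(trials$subject_id %in% excluded), , drop = FALSE],
       excluded = excluded,
       log = log[order(log$subject_id, log$intervention), ])
}

#' One-way repeated-measures ANOVA with partial eta squared
#'
#' Classical within-subject decomposition of an n-subjects by k-conditions
#' matrix: total sum of squares split into subject, condition and error
#' strata; `F = MS_cond / MS_error` on (k-1, (k-1)(n-1)) degrees of freedom;
#' partial eta squared is `SS_cond / (SS_cond + SS_error)`. No sphericity
#' correction is applied by default (`gg_correction = TRUE` applies
#' Greenhouse-Geisser adjusted degrees of freedom to the p-value).
#'
#' Experimental: `bf_bic = TRUE` adds `bf10_bic`, the BIC-approximate Bayes
#' factor for the condition effect (unit-information prior;
#' `exp((BIC_null - BIC_cond)/2)` with the subject stratum in both models).
#' This is NOT comparable to Bayes factors computed with default Cauchy
#' priors (e.g. JASP's); it is offered only as a rough order-of-magnitude
#' device.
#'
#' @param data Numeric matrix or data.frame, rows = subjects, columns =
#'   conditions, complete cases only.
#' @param gg_correction Apply Greenhouse-Geisser correction to the p-value?
#' @param bf_bic Also report the experimental BIC-approximate Bayes factor?
#' @return An object of class `rm_anova_result`: F, df_num, df_den, p,
#'   eta_p_sq, condition_means, n (and `bf10_bic` when requested).
#' @examples
#' m <- cbind(a = rnorm(20), b = rnorm(20), c = rnorm(20))
#' rm_anova_oneway(m)
#' @export
rm_anova_oneway <- function(data, gg_correction = FALSE, bf_bic = FALSE) {
  y <- as.matrix(data)
  if (anyNA(y)) stop("complete data required; apply listwise deletion upstream")
  n <- nrow(y); k <- ncol(y)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 conditions")
  grand <- mean(y)
  ss_subj <- k * sum((rowMeans(y) - grand)^2)
  ss_cond <- n * sum((colMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  ss_err <- max(ss_err, 0)   # guard tiny negative rounding
  df_num <- k - 1L; df_den <- (k - 1L) * (n - 1L)
  ms_cond <- ss_cond / df_num; ms_err <- ss_err / df_den

  if (ms_err == 0 && ms_cond == 0) {
    warning("constant within-subject data; reporting F = 0, p = 1")
    f <- 0; p <- 1; eta <- 0
  } else if (ms_err == 0) {
    warning("zero error variance with a nonzero effect; F reported as Inf")
    f <- Inf; p <- 0; eta <- 1
  } else {
    f <- ms_cond / ms_err
    eta <- ss_cond / (ss_cond + ss_err)
    if (gg_correction) {
      eps <- gg_epsilon(y)
      p <- stats::pf(f, eps * df_num, eps * df_den, lower.tail = FALSE)
    } else {
      p <- stats::pf(f, df_num, df_den, lower.tail = FALSE)
    }
  }
  out <- list(F = f, df_num = df_num, df_den = df_den, p = p,
              eta_p_sq = eta, condition_means = colMeans(y), n = n,
              gg_correction = gg_correction)
  if (bf_bic) {
    # unit-information BIC approximation: both models keep the subject
    # stratum; the alternative adds k-1 condition parameters
    N <- n * k
    ss0 <- ss_cond + ss_err
    out$bf10_bic <- if (ss_err > 0)
      exp((N * log(ss0 / ss_err) - df_num * log(N)) / 2) else NA_real_
  }
  structure(out, class = "rm_anova_result")
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix
gg_epsilon <- function(y) {
  S <- stats::cov(y)
  k <- ncol(S)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("RM-ANOVA: F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f (n = %d)\n",
              x$df_num, x$df_den, x$F, x$p, x$eta_p_sq, x$n))
  invisible(x)
}

#' Stay tables for every subject-session of a cohort
#'
#' @param trials Cohort trial table.
#' @return `data.frame`: subject_id, intervention, the four cells, their
#'   counts, mf_effect, mb_effect.
#' @export
cohort_stay_tables <- function(trials) {
  keys <- unique(trials[, c("subject_id", "intervention")])
  keys <- keys[order(keys$subject_id, keys$intervention), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- trials[trials$subject_id == keys$subject_id[i] &
                    trials$intervention == keys$intervention[i], , drop = FALSE]
    st <- stay_table(sub)
    data.frame(subject_id = keys$subject_id[i],
               intervention = keys$intervention[i],
               p_com_plus = st$p_com_plus, p_rar_plus = st$p_rar_plus,
               p_com_minus = st$p_com_minus, p_rar_minus = st$p_rar_minus,
               n_com_plus = st$n_cell[["com_plus"]],
               n_rar_plus = st$n_cell[["rar_plus"]],
               n_com_minus = st$n_cell[["com_minus"]],
               n_rar_minus = st$n_cell[["rar_minus"]],
               mf_effect = st$mf_effect, mb_effect = st$mb_effect,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Intervention ANOVAs on behavioural scores and fitted parameters
#'
#' Runs the one-way within-subject ANOVA (intervention as the k-level factor)
#' on the model-free effect, the model-based effect, and each of the seven
#' fitted parameters. Subjects lacking any intervention's entry are dropped
#' with a log entry.
#'
#' @param fits Per-session fit table from [fit_cohort()].
#' @param staytables Per-session stay-table frame from
#'   [cohort_stay_tables()].
#' @param gg_correction Passed to [rm_anova_oneway()].
#' @return List with `report` (one row per outcome: outcome, F, df_num,
#'   df_den, p, eta_p_sq, n) and `dropped` (subject ids without complete
#'   sessions).
#' @export
intervention_analysis <- function(fits, staytables, gg_correction = FALSE) {
  outcomes <- c(mf_effect = "mf_effect", mb_effect = "mb_effect",
                stats::setNames(param_names, param_names))
  dropped <- character()
  rows <- lapply(names(outcomes), function(nm) {
    src <- if (nm %in% c("mf_effect", "mb_effect")) staytables else fits
    wide <- stats::reshape(src[, c("subject_id", "intervention", nm)],
                           idvar = "subject_id", timevar = "intervention",
                           direction = "wide")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    ok <- stats::complete.cases(mat)
    dropped <<- union(dropped, wide$subject_id[!ok])
    mat <- mat[ok, , drop = FALSE]
    if (nrow(mat) < 2L)
      stop("fewer than 2 subjects with complete sessions for outcome ", nm)
    res <- rm_anova_oneway(mat, gg_correction = gg_correction)
    data.frame(outcome = nm, F = res$F, df_num = res$df_num,
               df_den = res$df_den, p = res$p, eta_p_sq = res$eta_p_sq,
               n = res$n, stringsAsFactors = FALSE)
  })
  list(report = do.call(rbind, rows), dropped = dropped)
}
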