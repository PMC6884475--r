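#' Two-way mixed repeated-measures ANOVA
#'
#' Classical sums-of-squares mixed ANOVA with one between-subjects factor
#' (training condition) and one within-subjects factor (e.g. first/last
#' trial or pretest/posttest), on a balanced long-format table. Reported
#' degrees of freedom follow the convention of the driving literature:
#' with `a` groups of `n` subjects and `b` within levels, the
#' between-subjects effect is tested on `(a - 1, a(n - 1))` df and the
#' within and interaction effects on `(b - 1, (b - 1) a (n - 1))` and
#' `((a - 1)(b - 1), (b - 1) a (n - 1))` df. Within-subject effects are
#' Greenhouse-Geisser corrected (vacuous at `b = 2`, where epsilon is
#' exactly 1). Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long-format data frame: one row per participant x within
#'   level.
#' @param value,participant,between,within Column names (strings).
#' @return An `lk_anova` object; `tidy()` returns the effect table with
#'   columns `effect`, `ss`, `df1`, `df2`, `statistic` (F), `gg_epsilon`,
#'   `p.value`, `partial_eta_sq`.
#' @examples
#' tbl <- simulate_null_table(n_per_group = 5, seed = 1)
#' tidy(mixed_anova(tbl))
#' @export
mixed_anova <- function(data, value = "value", participant = "participant",
                        between = "group", within = "phase") {
  need <- c(value, participant, between, within)
  if (!all(need %in% names(data))) {
    stop("missing columns: ", paste(setdiff(need, names(data)), collapse = ", "),
         call. = FALSE)
  }
  y <- data[[value]]
  id <- as.character(data[[participant]])
  A <- as.character(data[[between]])
  B <- as.character(data[[within]])
  if (any(!is.finite(y))) stop("non-finite values in the response", call. = FALSE)

  a_lv <- unique(A); b_lv <- unique(B)
  a <- length(a_lv); b <- length(b_lv)
  if (a < 2 || b < 2) stop("need at least 2 levels per factor", call. = FALSE)
  # balanced, fully crossed within-subject design
  tab <- table(id, B)
  if (any(tab != 1)) {
    stop("unsupported design: each participant needs exactly one value per within level",
         call. = FALSE)
  }
  grp_of <- tapply(A, id, function(g) unique(g))
  if (any(lengths(grp_of) != 1)) {
    stop("unsupported design: participants must belong to exactly one group",
         call. = FALSE)
  }
  n_per <- table(unlist(grp_of))
  if (length(unique(as.integer(n_per))) != 1) {
    stop("unsupported design: groups must be balanced", call. = FALSE)
  }
  n <- as.integer(n_per[1])
  if (n < 2) stop("need at least 2 participants per group", call. = FALSE)

  grand <- mean(y)
  subj_mean <- tapply(y, id, mean)
  grp_mean <- tapply(y, A, mean)
  within_mean <- tapply(y, B, mean)
  cell_mean <- tapply(y, list(A, B), mean)

  ss_total <- sum((y - grand)^2)
  ss_subj <- b * sum((subj_mean - grand)^2)
  ss_a <- n * b * sum((grp_mean - grand)^2)
  ss_sa <- ss_subj - ss_a
  ss_b <- n * a * sum((within_mean - grand)^2)
  ss_ab <- n * sum((sweep(sweep(cell_mean, 1, grp_mean[rownames(cell_mean)]),
                          2, within_mean[colnames(cell_mean)]) + grand)^2)
  ss_bsa <- ss_total - ss_subj - ss_b - ss_ab

  # Greenhouse-Geisser epsilon from the pooled within-level covariance
  wide <- matrix(NA_real_, nrow = length(unique(id)), ncol = b,
                 dimnames = list(unique(id), b_lv))
  for (r in seq_along(y)) wide[id[r], B[r]] <- y[r]
  grp_vec <- unlist(grp_of)[rownames(wide)]
  centered <- wide
  for (g in a_lv) {
    rows <- grp_vec == g
    centered[rows, ] <- sweep(wide[rows, , drop = FALSE], 2,
                              colMeans(wide[rows, , drop = FALSE]))
  }
  S <- crossprod(centered) / (a * (n - 1))
  eps <- gg_epsilon(S)

  df_a <- a - 1; df_sa <- a * (n - 1)
  df_b <- b - 1; df_ab <- (a - 1) * (b - 1); df_bsa <- (b - 1) * a * (n - 1)
  # an exactly-null effect reports F = 0 even when its error term is zero
  fstat <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_eff <= 1e-300) return(0)
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  f_a <- fstat(ss_a, df_a, ss_sa, df_sa)
  f_b <- fstat(ss_b, df_b, ss_bsa, df_bsa)
  f_ab <- fstat(ss_ab, df_ab, ss_bsa, df_bsa)

  table <- tibble::tibble(
    effect = c(between, within, paste0(between, ":", within)),
    ss = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_sa, ss_bsa, ss_bsa),
    df1 = c(df_a, df_b, df_ab),
    df2 = c(df_sa, df_bsa, df_bsa),
    statistic = c(f_a, f_b, f_ab),
    gg_epsilon = c(NA_real_, eps, eps),
    p.value = c(
      pf(f_a, df_a, df_sa, lower.tail = FALSE),
      pf(f_b, df_b * eps, df_bsa * eps, lower.tail = FALSE),
      pf(f_ab, df_ab * eps, df_bsa * eps, lower.tail = FALSE)
    ),
    partial_eta_sq = c(ss_a / (ss_a + ss_sa),
                       ss_b / (ss_b + ss_bsa),
                       ss_ab / (ss_ab + ss_bsa))
  )
  structure(
    list(table = table, ss_total = ss_total,
         design = list(a = a, b = b, n = n, between = between,
                       within = within, a_levels = a_lv, b_levels = b_lv)),
    class = "lk_anova"
  )
}

#' @export
print.lk_anova <- function(x, ...) {
  d <- x$design
  cat(sprintf("Mixed ANOVA: %d groups x %d within levels, n = %d per group\n",
              d$a, d$b, d$n))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' @export
tidy.lk_anova <- function(x, ...) x$table

#' @export
glance.lk_anova <- function(x, ...) {
  d <- x$design
  tibble::tibble(n_groups = d$a, n_within = d$b, n_per_group = d$n,
                 ss_total = x$ss_total)
}

#' Greenhouse-Geisser epsilon (Box's estimator)
#'
#' Sphericity correction factor for repeated-measures F tests, computed
#' from the covariance matrix of the within-subject levels:
#' `eps = tr(D)^2 / ((k - 1) * sum(D^2))` with `D` the double-centered
#' covariance. Bounded to `[1/(k - 1), 1]`; exactly 1 for a two-level
#' within factor (sphericity is vacuous) and for compound-symmetric
#' covariance.
#'
#' @param within_covariance Symmetric covariance matrix over the `k` within
#'   levels.
#' @return Epsilon in `(1/(k - 1), 1]`.
#' @examples
#' gg_epsilon(diag(2))  # always 1 at k = 2
#' @export
gg_epsilon <- function(within_covariance) {
  S <- as.matrix(within_covariance)
  k <- ncol(S)
  if (k != nrow(S)) stop("covariance must be square", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  if (k < 2) return(1)
  C <- diag(k) - matrix(1 / k, k, k)
  D <- C %*% S %*% C
  denom <- (k - 1) * sum(D^2)
  if (denom < 1e-300) return(1)
  clamp(sum(diag(D))^2 / denom, 1 / (k - 1), 1)
}

#' Simple main effects after a significant interaction
#'
#' Tests the within-subject factor separately at each between level (df
#' `(b - 1, (n - 1)(b - 1))`, e.g. F(1, 14) within one group of 15), and
#' the between factor separately at each within level using the one-way
#' between-groups error at that level (df `(a - 1, a(n - 1))`, e.g.
#' F(2, 42)).
#'
#' @inheritParams mixed_anova
#' @param significant_interaction Set `FALSE` to force an empty result, as
#'   simple effects are only warranted after a significant interaction.
#' @return A tibble with columns `stratum`, `effect`, `df1`, `df2`,
#'   `statistic`, `p.value`, `partial_eta_sq`.
#' @export
simple_main_effects <- function(data, value = "value",
                                participant = "participant",
                                between = "group", within = "phase",
                                significant_interaction = TRUE) {
  if (!isTRUE(significant_interaction)) {
    return(tibble::tibble(stratum = character(), effect = character(),
                          df1 = numeric(), df2 = numeric(),
                          statistic = numeric(), p.value = numeric(),
                          partial_eta_sq = numeric()))
  }
  y <- data[[value]]
  id <- as.character(data[[participant]])
  A <- as.character(data[[between]])
  B <- as.character(data[[within]])
  a_lv <- unique(A); b_lv <- unique(B)
  out <- list()
  # within-factor effect inside each group: one-way repeated measures
  for (g in a_lv) {
    sel <- A == g
    yg <- y[sel]; idg <- id[sel]; bg <- B[sel]
    n <- length(unique(idg)); b <- length(b_lv)
    grand <- mean(yg)
    sm <- tapply(yg, idg, mean); bm <- tapply(yg, bg, mean)
    ss_b <- n * sum((bm - grand)^2)
    ss_err <- sum((yg - sm[idg] - bm[bg] + grand)^2)
    df1 <- b - 1; df2 <- (n - 1) * (b - 1)
    f <- if (ss_b <= 1e-300) 0 else (ss_b / df1) / (ss_err / df2)
    out[[length(out) + 1]] <- tibble::tibble(
      stratum = paste0(between, "=", g), effect = within,
      df1 = df1, df2 = df2, statistic = f,
      p.value = pf(f, df1, df2, lower.tail = FALSE),
      partial_eta_sq = ss_b / (ss_b + ss_err)
    )
  }
  # between-factor effect at each within level: one-way between groups
  for (k in b_lv) {
    sel <- B == k
    yk <- y[sel]; ak <- A[sel]
    a <- length(a_lv); n <- sum(ak == a_lv[1])
    grand <- mean(yk)
    gm <- tapply(yk, ak, mean)
    ss_a <- n * sum((gm - grand)^2)
    ss_err <- sum((yk - gm[ak])^2)
    df1 <- a - 1; df2 <- a * (n - 1)
    f <- if (ss_a <= 1e-300) 0 else (ss_a / df1) / (ss_err / df2)
    out[[length(out) + 1]] <- tibble::tibble(
      stratum = paste0(within, "=", k), effect = between,
      df1 = df1, df2 = df2, statistic = f,
      p.value = pf(f, df1, df2, lower.tail = FALSE),
      partial_eta_sq = ss_a / (ss_a + ss_err)
    )
  }
  dplyr::bind_rows(out)
}

# Pairwise group comparisons at one within level, pooled one-way error
# (df = a(n - 1)), two-sided p-values.
pairwise_group_t <- function(data, level, value = "value",
                             participant = "participant",
                             between = "group", within = "phase") {
  sel <- as.character(data[[within]]) == level
  yk <- data[[value]][sel]
  ak <- as.character(data[[between]])[sel]
  a_lv <- unique(ak); a <- length(a_lv)
  n <- sum(ak == a_lv[1])
  gm <- tapply(yk, ak, mean)
  mse <- sum((yk - gm[ak])^2) / (a * (n - 1))
  pairs <- utils::combn(a_lv, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    tt <- (gm[[g1]] - gm[[g2]]) / sqrt(mse * 2 / n)
    tibble::tibble(
      stratum = paste0(within, "=", level),
      comparison = paste(g1, "vs", g2),
      estimate = gm[[g1]] - gm[[g2]],
      statistic = tt, df = a * (n - 1),
      p.value = 2 * pt(abs(tt), a * (n - 1), lower.tail = FALSE)
    )
  })
}

# All attainable numbers of true null hypotheses among the k(k-1)/2
# pairwise equalities of k means: sums of choose(m, 2) over the blocks of
# each partition of k.
possible_true_counts <- function(k) {
  parts <- function(n, max_part) {
    if (n == 0) return(list(integer()))
    out <- list()
    for (p in seq_len(min(n, max_part))) {
      for (rest in parts(n - p, p)) out[[length(out) + 1]] <- c(p, rest)
    }
    out
  }
  sort(unique(vapply(parts(k, k),
                     function(p) sum(choose(p, 2)), numeric(1))))
}

#' Shaffer's modified sequentially rejective Bonferroni procedure
#'
#' Multiple-comparison procedure for the family of all pairwise equalities
#' among `k` group means. P-values are ordered ascending; at step `i` the
#' threshold is `alpha / t_i`, where `t_i` is the largest number of null
#' hypotheses that could simultaneously be true given that `i - 1` have
#' been rejected (Shaffer's S1, computed from the partition structure of
#' pairwise families). For `k = 3` the multipliers are 3, 1, 1: after the
#' smallest p-value is rejected at `alpha / 3`, the two remaining
#' hypotheses cannot both be true, so each is tested at `alpha`. The
#' procedure stops at the first failure. Uniformly at least as powerful as
#' Holm on pairwise families.
#'
#' @param pvals Numeric vector of unadjusted p-values, one per pairwise
#'   comparison (length `k(k-1)/2`).
#' @param k_groups Number of group means compared.
#' @param alpha Family-wise error level (default 0.05).
#' @param labels Optional comparison labels.
#' @return A tibble in the input order with columns `comparison`,
#'   `p.value`, `multiplier`, `p.adjusted` (monotone step-down adjusted
#'   p), `reject`.
#' @examples
#' shaffer_multicomp(c(0.001, 0.04, 0.2), k_groups = 3)
#' @export
shaffer_multicomp <- function(pvals, k_groups, alpha = 0.05, labels = NULL) {
  m <- length(pvals)
  if (m != choose(k_groups, 2)) {
    stop("`pvals` must have one entry per pairwise comparison", call. = FALSE)
  }
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("H", seq_len(m))
  S <- possible_true_counts(k_groups)
  multipliers <- vapply(seq_len(m), function(i) {
    max(S[S <= m - (i - 1)])
  }, numeric(1))
  ord <- order(pvals)
  p_sorted <- pvals[ord]
  p_adj_sorted <- pmin(cummax(multipliers * p_sorted), 1)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (multipliers[i] * p_sorted[i] <= alpha) {
      reject_sorted[i] <- TRUE
    } else {
      break
    }
  }
  out <- tibble::tibble(
    comparison = labels[ord], p.value = p_sorted,
    multiplier = multipliers, p.adjusted = p_adj_sorted,
    reject = reject_sorted
  )
  out[order(ord), ]
}

#' Synthetic null long table for calibration checks
#'
#' Generates a balanced long-format table (3 groups x `n_per_group`
#' participants x 2 within levels) in which every group follows the same
#' generative process (random participant intercept plus residual noise):
#' the global null for the mixed ANOVA. Used to verify the pipeline's
#' type-I error rate against the nominal alpha.
#'
#' @param n_per_group Participants per group (default 15).
#' @param seed Integer seed.
#' @param mean Grand mean of the response.
#' @param sd_subject Between-participant intercept SD.
#' @param sd_noise Residual SD.
#' @return A tibble with columns `participant`, `group`, `phase`, `value`.
#' @export
simulate_null_table <- function(n_per_group = 15, seed = NULL, mean = 0.3,
                                sd_subject = 0.08, sd_noise = 0.05) {
  with_seed(seed, {
    groups <- c("ND", "VO", "SS")
    purrr::map_dfr(groups, function(g) {
      purrr::map_dfr(seq_len(n_per_group), function(i) {
        intercept <- mean + rnorm(1, 0, sd_subject)
        tibble::tibble(
          participant = sprintf("%s%02d", g, i), group = g,
          phase = c("first", "last"),
          value = intercept + rnorm(2, 0, sd_noise)
        )
      })
    })
  })
}

#' Full inferential analysis of an experiment's metrics table
#'
#' Runs, for each performance metric (SDLP and SWV), the two planned
#' two-way mixed repeated-measures ANOVAs: *training* (first vs last
#' training trial) and *interference* (last pretest trial vs first posttest
#' trial), each with training condition as the between-subjects factor.
#' When an interaction is significant at `alpha`, simple main effects are
#' computed, followed by pairwise group comparisons at each within level
#' (pooled stratum error, df `a(n-1)`) adjusted with
#' [shaffer_multicomp()].
#'
#' @param metrics A metrics table as produced by [run_experiment()]:
#'   columns `participant`, `group`, `session`
#'   (`pretest`/`training`/`posttest`), `trial`, `sdlp`, `swv`.
#' @param alpha Significance threshold (default 0.05).
#' @return An `lk_analysis` object: nested list
#'   `$<metric>$<analysis>` with elements `anova` (an `lk_anova`),
#'   `simple_effects` and `comparisons` (tibbles, present when the
#'   interaction was significant); `tidy()` flattens all effect tables.
#' @export
analyze_experiment <- function(metrics, alpha = 0.05) {
  need <- c("participant", "group", "session", "trial", "sdlp", "swv")
  if (!all(need %in% names(metrics))) {
    stop("metrics table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (s in c("pretest", "training", "posttest")) {
    if (!any(metrics$session == s)) {
      stop("missing session: ", s, call. = FALSE)
    }
  }
  slice_phase <- function(session, trial, phase) {
    m <- metrics[metrics$session == session & metrics$trial == trial, ]
    tibble::tibble(participant = m$participant, group = m$group,
                   phase = phase, sdlp = m$sdlp, swv = m$swv)
  }
  n_training <- max(metrics$trial[metrics$session == "training"])
  n_pretest <- max(metrics$trial[metrics$session == "pretest"])
  designs <- list(
    training = dplyr::bind_rows(
      slice_phase("training", 1, "first"),
      slice_phase("training", n_training, "last")
    ),
    interference = dplyr::bind_rows(
      slice_phase("pretest", n_pretest, "pretest"),
      slice_phase("posttest", 1, "posttest")
    )
  )
  res <- purrr::map(c(sdlp = "sdlp", swv = "swv"), function(metric) {
    purrr::map(designs, function(d) {
      d$value <- d[[metric]]
      if (any(is.na(d$value))) {
        stop("missing ", metric, " values in the analysis slice", call. = FALSE)
      }
      an <- mixed_anova(d)
      inter_p <- an$table$p.value[3]
      if (is.finite(inter_p) && inter_p < alpha) {
        se <- simple_main_effects(d)
        cmp <- purrr::map_dfr(unique(d$phase), function(lv) {
          pt <- pairwise_group_t(d, lv)
          adj <- shaffer_multicomp(pt$p.value, k_groups = an$design$a,
                                   alpha = alpha, labels = pt$comparison)
          dplyr::left_join(pt, adj[, c("comparison", "multiplier",
                                       "p.adjusted", "reject")],
                           by = "comparison")
        })
        list(anova = an, simple_effects = se, comparisons = cmp)
      } else {
        list(anova = an, simple_effects = NULL, comparisons = NULL)
      }
    })
  })
  structure(list(results = res, alpha = alpha), class = "lk_analysis")
}

#' @export
tidy.lk_analysis <- function(x, ...) {
  purrr::map_dfr(names(x$results), function(metric) {
    purrr::map_dfr(names(x$results[[metric]]), function(an) {
      tbl <- x$results[[metric]][[an]]$anova$table
      dplyr::bind_cols(tibble::tibble(metric = metric, analysis = an,
                                      .rows = nrow(tbl)), tbl)
    })
  })
}

#' @export
print.lk_analysis <- function(x, ...) {
  for (metric in names(x$results)) {
    for (an in names(x$results[[metric]])) {
      r <- x$results[[metric]][[an]]
      cat(sprintf("== %s, %s analysis ==\n", toupper(metric), an))
      print(as.data.frame(r$anova$table), digits = 4)
      if (!is.null(r$simple_effects)) {
        cat("-- simple main effects --\n")
        print(as.data.frame(r$simple_effects), digits = 4)
      }
      if (!is.null(r$comparisons)) {
        cat("-- pairwise comparisons (Shaffer) --\n")
        print(as.data.frame(r$comparisons), digits = 4)
      }
      cat("\n")
    }
  }
  invisible(x)
}

#' Export an analysis as JSON
#'
#' @param analysis An `lk_analysis` from [analyze_experiment()].
#' @param path File path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_results_json <- function(analysis, path = NULL) {
  stopifnot(inherits(analysis, "lk_analysis"))
  obj <- purrr::map(analysis$results, function(metric_res) {
    purrr::map(metric_res, function(r) {
      list(
        effects = r$anova$table,
        simple_effects = r$simple_effects,
        comparisons = r$comparisons
      )
    })
  })
  json <- jsonlite::toJSON(list(alpha = analysis$alpha, results = obj),
                           auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}
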