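#' Nonparametric comparison of decoding models
#'
#' The run-level statistical layer: per metric, Shapiro-Wilk normality
#' screening of every model's run distribution, Kruskal-Wallis tests over
#' the pre-drug model and the three post-drug models of each drug family
#' (df = 3 per family), and Dunn-type pairwise rank comparisons with
#' Bonferroni family-wise correction.
#'
#' @param metrics data.frame with columns `condition`, `run` and one
#'   column per metric (as produced by [run_experiment()]).
#' @param metric_names Metrics to analyse.
#' @return A `stat_report`: per metric a list with `shapiro` (data.frame),
#'   `kruskal` (data.frame: family, chisq, df, p), `posthoc` (data.frame
#'   of pairwise Dunn z tests with Bonferroni-adjusted p) and `notes`.
#' @export
compare_models <- function(metrics,
                           metric_names = c("accuracy", "sensitivity",
                                            "specificity")) {
  conds <- unique(metrics$condition)
  if (length(conds) < 2) stopf("need at least two models to compare")
  families <- list(
    MM = intersect(c("pre", "MM30", "MM60", "MM90"), conds),
    PM = intersect(c("pre", "PM30", "PM60", "PM90"), conds)
  )
  families <- Filter(function(f) length(f) >= 2, families)
  report <- list()
  for (met in metric_names) {
    notes <- character(0)
    sh <- do.call(rbind, lapply(conds, function(cond) {
      x <- metrics[[met]][metrics$condition == cond]
      if (length(x) < 3) return(NULL)
      if (stats::sd(x) == 0) {
        notes <<- c(notes, sprintf("Shapiro-Wilk skipped for constant group '%s'", cond))
        return(data.frame(condition = cond, W = NA_real_, p = NA_real_))
      }
      t <- stats::shapiro.test(x)
      data.frame(condition = cond, W = unname(t$statistic), p = t$p.value)
    }))
    kw <- list()
    ph <- list()
    for (fam in names(families)) {
      groups <- families[[fam]]
      sub <- metrics[metrics$condition %in% groups, ]
      kt <- stats::kruskal.test(sub[[met]], factor(sub$condition, levels = groups))
      kw[[fam]] <- data.frame(family = fam,
                              chisq = unname(kt$statistic),
                              df = unname(kt$parameter), p = kt$p.value)
      ph[[fam]] <- dunn_pairwise(sub[[met]],
                                 factor(sub$condition, levels = groups), fam)
    }
    report[[met]] <- list(shapiro = sh, kruskal = do.call(rbind, kw),
                          posthoc = do.call(rbind, ph), notes = notes)
  }
  structure(report, class = "stat_report")
}

# Dunn's pairwise rank test over all group pairs with Bonferroni
# correction sized by the number of pairs in the family.
dunn_pairwise <- function(x, g, family = "") {
  r <- rank(x)
  n <- length(x)
  # tie correction for the rank variance
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    na <- sum(g == a); nb <- sum(g == b)
    z <- (mean(r[g == a]) - mean(r[g == b])) / sqrt(v0 * (1 / na + 1 / nb))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(family = family, group1 = a, group2 = b, z = z,
               p = p, p_adj = min(1, p * m))
  })
  do.call(rbind, out)
}

#' Repeated-measures 2x3 ANOVA over post-drug models
#'
#' Box-Cox transforms the run-level metric values (maximum-likelihood
#' lambda; an all-positive shift is applied automatically when needed)
#' and fits a drug (morphine/placebo) x time (30/60/90 min) ANOVA with
#' the run index as the repeated-measures error stratum.
#'
#' @param metrics data.frame as in [compare_models()], restricted or not;
#'   only the six post-drug conditions are used.
#' @param metric Metric column to analyse.
#' @return List: `lambda`, `lambda_ci` (95% profile interval), `shift`,
#'   and `anova` (data.frame with F and p for drug, time, drug:time).
#' @export
anova_2x3 <- function(metrics, metric = "accuracy") {
  post <- metrics[metrics$condition %in% c("MM30", "MM60", "MM90",
                                           "PM30", "PM60", "PM90"), ]
  if (!nrow(post)) stopf("no post-drug conditions in metrics")
  counts <- table(post$condition)
  if (length(counts) != 6 || length(unique(counts)) != 1) {
    stopf("need all six post-drug groups with equal run counts")
  }
  y <- post[[metric]]
  if (!all(is.finite(y))) stopf("non-finite metric values")
  shift <- 0
  if (min(y) <= 0) shift <- 1e-6 - min(y)
  yp <- y + shift
  drug <- factor(ifelse(grepl("^MM", post$condition), "morphine", "placebo"))
  time <- factor(sub("^(MM|PM)", "", post$condition), levels = c("30", "60", "90"))
  run <- factor(post$run)
  bc_df <- data.frame(yp = yp, drug = drug, time = time)
  bc <- MASS::boxcox(yp ~ drug * time, data = bc_df, lambda = seq(-5, 5, 0.01),
                     plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  in_ci <- bc$y > max(bc$y) - stats::qchisq(0.95, 1) / 2
  lambda_ci <- range(bc$x[in_ci])
  yt <- if (abs(lambda) < 1e-8) log(yp) else (yp^lambda - 1) / lambda
  fit <- stats::aov(yt ~ drug * time + Error(run))
  sm <- summary(fit)
  within <- sm[["Error: Within"]][[1]]
  rn <- trimws(rownames(within))
  pick <- function(term) {
    i <- match(term, rn)
    data.frame(term = term, df = within$Df[i], F = within$`F value`[i],
               p = within$`Pr(>F)`[i])
  }
  list(
    lambda = lambda, lambda_ci = lambda_ci, shift = shift,
    anova = rbind(pick("drug"), pick("time"), pick("drug:time"))
  )
}

#' Maximum-likelihood Box-Cox lambda of a sample
#'
#' Convenience wrapper used in calibration checks: profile-likelihood
#' lambda and 95% interval for a positive sample under a constant-mean
#' model.
#'
#' @param y Positive numeric vector.
#' @return List with `lambda` and `ci`.
#' @export
boxcox_lambda <- function(y) {
  if (min(y) <= 0) stopf("Box-Cox requires positive values")
  bc <- MASS::boxcox(y ~ 1, data = data.frame(y = y),
                     lambda = seq(-5, 5, 0.01), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  in_ci <- bc$y > max(bc$y) - stats::qchisq(0.95, 1) / 2
  list(lambda = lambda, ci = range(bc$x[in_ci]))
}

#' @export
print.stat_report <- function(x, ...) {
  for (met in names(x)) {
    cat(sprintf("== %s ==\n", met))
    cat("Kruskal-Wallis:\n")
    print(x[[met]]$kruskal, row.names = FALSE)
    cat("Post hoc (Dunn z, Bonferroni-adjusted):\n")
    print(x[[met]]$posthoc, row.names = FALSE, digits = 3)
    if (length(x[[met]]$notes)) cat(paste(x[[met]]$notes, collapse = "\n"), "\n")
  }
  invisible(x)
}
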