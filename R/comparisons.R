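# Region- and cluster-comparison battery: Shapiro-Wilk gate, one-way
# ANOVA with Tukey-Kramer letters, Kruskal-Wallis with Dunn post hoc,
# Fisher's exact with Bonferroni pairwise, and covariate-adjusted
# two-way ANOVA across housing clusters.

#' Normality gate for choosing the comparison family
#'
#' Shapiro-Wilk at alpha = 0.05 on the residuals from group means (the
#' pooled within-group deviations), deciding between the parametric
#' (ANOVA/Tukey) and rank-based (Kruskal-Wallis/Dunn) battery. Constant
#' data are non-normal by convention.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param alpha Gate level (default 0.05).
#' @return List: `decision` ("normal"/"non-normal"), `p`, `statistic`.
#' @export
normality_gate <- function(values, groups, alpha = 0.05) {
  if (length(values) < 3) stop("at least 3 observations are required")
  stopifnot(length(values) == length(groups))
  resid <- values - stats::ave(values, groups)
  if (stats::sd(resid) == 0)
    return(list(decision = "non-normal", p = NA_real_, statistic = NA_real_))
  sw <- stats::shapiro.test(resid)
  list(decision = if (sw$p.value >= alpha) "normal" else "non-normal",
       p = sw$p.value, statistic = unname(sw$statistic))
}

# Compact letter display from a symmetric pairwise p-value matrix:
# insert-and-absorb. Groups sharing a letter are not significantly
# different at alpha.
.letter_display <- function(pmat, alpha = 0.05) {
  g <- rownames(pmat)
  sets <- list(g)
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      if (j <= i) next
      if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
      new_sets <- list()
      for (s in sets) {
        if (g[i] %in% s && g[j] %in% s) {
          new_sets <- c(new_sets, list(setdiff(s, g[i])), list(setdiff(s, g[j])))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb sets contained in another
      keep <- vapply(seq_along(new_sets), function(a) {
        !any(vapply(seq_along(new_sets), function(b) {
          a != b && all(new_sets[[a]] %in% new_sets[[b]]) &&
            !(all(new_sets[[b]] %in% new_sets[[a]]) && a < b)
        }, logical(1)))
      }, logical(1))
      sets <- new_sets[keep]
    }
  }
  letters_out <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(sets)) {
    for (memb in sets[[k]]) {
      letters_out[memb] <- paste0(letters_out[memb], letters[k])
    }
  }
  letters_out
}

#' One-way ANOVA with Tukey-Kramer letters
#'
#' Overall F test, then Tukey-Kramer pairwise comparisons (studentised
#' range, valid for unequal group sizes) summarised as a compact letter
#' display at alpha = 0.05. Groups with fewer than 2 observations are
#' excluded with a warning.
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param alpha Level for the letter display.
#' @return List of class `shed_comparison`: test name, statistic (F),
#'   df, p, `pairwise` (Tukey adjusted p per pair), `letters`,
#'   `summary` (per-group n/mean/sd), adjustment method.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding groups with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("at least 2 groups are required")
  g <- factor(groups)
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pair_names <- rownames(tk)
  lv <- levels(g)
  pmat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (r in seq_along(pair_names)) {
    ab <- strsplit(pair_names[r], "-", fixed = TRUE)[[1]]
    # group labels may themselves contain '-': split on the boundary that
    # yields two known levels
    if (length(ab) != 2 || !all(ab %in% lv)) {
      hit <- FALSE
      for (cut in seq_len(nchar(pair_names[r]) - 1)) {
        a <- substr(pair_names[r], 1, cut)
        b <- substr(pair_names[r], cut + 2, nchar(pair_names[r]))
        if (a %in% lv && b %in% lv &&
            substr(pair_names[r], cut + 1, cut + 1) == "-") {
          ab <- c(a, b); hit <- TRUE; break
        }
      }
      if (!hit) stop("cannot parse Tukey pair label: ", pair_names[r])
    }
    pmat[ab[1], ab[2]] <- pmat[ab[2], ab[1]] <- tk[r, "p adj"]
  }
  summary_tab <- do.call(rbind, lapply(split(values, g), function(x)
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x))))
  summary_tab <- cbind(group = rownames(summary_tab), summary_tab)
  rownames(summary_tab) <- NULL
  structure(list(test = "one-way ANOVA + Tukey-Kramer",
                 statistic = an[["F value"]][1],
                 df = c(an[["Df"]][1], an[["Df"]][2]),
                 p = an[["Pr(>F)"]][1],
                 pairwise = pmat,
                 letters = .letter_display(pmat, alpha),
                 summary = summary_tab,
                 adjustment = "tukey"), class = "shed_comparison")
}

#' Dunn pairwise rank tests
#'
#' z statistics on mean pooled ranks with the standard tie correction,
#' two-sided normal p-values, adjusted by `method` (default Holm).
#'
#' @param values Numeric observations.
#' @param groups Group labels.
#' @param method Adjustment passed to [stats::p.adjust()].
#' @return Data.frame: group pair, z, unadjusted and adjusted p.
#' @export
dunn_test <- function(values, groups, method = "holm") {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least 2 groups are required")
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, g, mean)
  n <- tapply(rk, g, length)
  pairs <- utils::combn(levels(g), 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[pr[1]] + 1 / n[pr[2]]))
    (rbar[pr[1]] - rbar[pr[2]]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = unname(z),
             p = unname(p), p_adjusted = stats::p.adjust(p, method),
             row.names = NULL)
}

#' Kruskal-Wallis with Dunn post hoc letters
#'
#' Overall Kruskal-Wallis H (tie-corrected), Dunn pairwise z tests with
#' Holm adjustment, and a compact letter display at alpha = 0.05.
#' All-identical values give H = 0, p = 1.
#'
#' @inheritParams anova_tukey
#' @param method Dunn p adjustment (default `"holm"`).
#' @return `shed_comparison` list as in [anova_tukey()]; the `summary`
#'   table reports medians.
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05, method = "holm") {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least 2 groups are required")
  if (length(unique(values)) == 1) {
    H <- 0; p <- 1
    pairs <- utils::combn(levels(g), 2)
    dn <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                     z = 0, p = 1, p_adjusted = 1)
  } else {
    kw <- stats::kruskal.test(values, g)
    H <- unname(kw$statistic); p <- kw$p.value
    dn <- dunn_test(values, groups, method)
  }
  lv <- levels(g)
  pmat <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (r in seq_len(nrow(dn)))
    pmat[dn$group1[r], dn$group2[r]] <- pmat[dn$group2[r], dn$group1[r]] <-
      dn$p_adjusted[r]
  summary_tab <- do.call(rbind, lapply(split(values, g), function(x)
    data.frame(n = length(x), median = stats::median(x),
               mean = mean(x), sd = stats::sd(x))))
  summary_tab <- cbind(group = rownames(summary_tab), summary_tab)
  rownames(summary_tab) <- NULL
  structure(list(test = "Kruskal-Wallis + Dunn",
                 statistic = H, df = nlevels(g) - 1, p = p,
                 pairwise = pmat, dunn = dn,
                 letters = .letter_display(pmat, alpha),
                 summary = summary_tab,
                 adjustment = method), class = "shed_comparison")
}

#' Fisher's exact battery for a group-by-category count table
#'
#' Overall exact test on the full R x C table (network algorithm; falls
#' back to Monte-Carlo with a fixed seed and 1e5 draws when the exact
#' computation is infeasible, and records which method was used),
#' followed by pairwise 2 x C Fisher tests between group rows with
#' Bonferroni multiplication by the number of pairs, and a letter
#' display at alpha = 0.05. Empty rows/columns are dropped with a
#' warning.
#'
#' @param counts Matrix of non-negative integer counts, groups in rows.
#' @param alpha Level for the letter display.
#' @return `shed_comparison` list: overall p, `pairwise` (Bonferroni-
#'   multiplied p), `letters`, `method` ("exact" or "monte-carlo").
#' @export
fisher_battery <- function(counts, alpha = 0.05) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  empty_r <- rowSums(counts) == 0
  empty_c <- colSums(counts) == 0
  if (any(empty_r) || any(empty_c)) {
    warning("dropping empty rows/columns")
    counts <- counts[!empty_r, !empty_c, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("at least a 2x2 table is required")
  run_fisher <- function(tab) {
    res <- tryCatch(
      list(p = stats::fisher.test(tab, workspace = 2e7)$p.value,
           method = "exact"),
      error = function(e) {
        set.seed(20170824)
        list(p = stats::fisher.test(tab, simulate.p.value = TRUE,
                                    B = 1e5)$p.value,
             method = "monte-carlo")
      })
    res
  }
  overall <- run_fisher(counts)
  g <- rownames(counts)
  if (is.null(g)) g <- as.character(seq_len(nrow(counts)))
  pairs <- utils::combn(seq_len(nrow(counts)), 2)
  npairs <- ncol(pairs)
  pmat <- matrix(NA_real_, nrow(counts), nrow(counts), dimnames = list(g, g))
  for (c2 in seq_len(npairs)) {
    i <- pairs[1, c2]; j <- pairs[2, c2]
    sub <- counts[c(i, j), , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    p_pair <- if (ncol(sub) < 2) 1 else run_fisher(sub)$p
    pmat[i, j] <- pmat[j, i] <- min(1, p_pair * npairs)
  }
  structure(list(test = "Fisher exact + Bonferroni pairwise",
                 statistic = NA_real_, p = overall$p,
                 method = overall$method,
                 pairwise = pmat,
                 letters = .letter_display(pmat, alpha),
                 summary = counts,
                 adjustment = "bonferroni"), class = "shed_comparison")
}

#' Covariate-adjusted two-way ANOVA across housing clusters
#'
#' Compares a microclimate response between housing clusters while
#' accounting for altitude and latitude: a linear model with the cluster
#' factor plus the covariates, Type-II sums of squares (clusters are
#' unbalanced). Only clusters with more than `min_size` members are
#' compared. Constant covariates (e.g. latitude within one region) are
#' dropped with a message.
#'
#' @param response Numeric response per farm.
#' @param cluster Cluster labels per farm.
#' @param altitude Altitude covariate, m.
#' @param latitude Latitude class covariate ("north"/"south").
#' @param min_size Minimum cluster size for inclusion (default 3,
#'   exclusive: clusters must have more than `min_size` members).
#' @return `shed_comparison` list with the cluster-effect F and p and
#'   the Type-II ANOVA table.
#' @export
cluster_twoway_anova <- function(response, cluster, altitude, latitude,
                                 min_size = 3) {
  stopifnot(length(response) == length(cluster))
  sizes <- table(cluster)
  eligible <- names(sizes)[sizes > min_size]
  if (length(eligible) < 2)
    stop("fewer than 2 clusters with more than ", min_size, " members")
  keep <- cluster %in% eligible
  df <- data.frame(y = response[keep],
                   cluster = factor(cluster[keep]),
                   altitude = altitude[keep],
                   latitude = factor(latitude[keep]))
  covars <- c("altitude", "latitude")
  constant <- vapply(covars, function(v) length(unique(df[[v]])) < 2, logical(1))
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(covars[constant], collapse = ", "))
    covars <- covars[!constant]
  }
  fml <- stats::reformulate(c("cluster", covars), response = "y")
  fit <- stats::lm(fml, data = df)
  a2 <- car::Anova(fit, type = 2)
  i <- match("cluster", rownames(a2))
  structure(list(test = "two-way ANOVA (Type II), altitude/latitude adjusted",
                 statistic = a2[i, "F value"], p = a2[i, "Pr(>F)"],
                 df = c(a2[i, "Df"], a2["Residuals", "Df"]),
                 anova_table = a2, model = fit,
                 clusters = eligible), class = "shed_comparison")
}

#' @export
print.shed_comparison <- function(x, ...) {
  cat(x$test, "\n")
  if (!is.na(x$statistic))
    cat(sprintf("  statistic = %.3f, p = %.4g\n", x$statistic, x$p))
  else cat(sprintf("  p = %.4g\n", x$p))
  if (!is.null(x$letters)) {
    cat("  letters:", paste(names(x$letters), x$letters, sep = ":",
                            collapse = "  "), "\n")
  }
  invisible(x)
}

#' Region comparison of one variable with the matching test family
#'
#' Applies the normality gate then either ANOVA/Tukey or
#' Kruskal-Wallis/Dunn; qualitative variables go to the Fisher battery
#' on their region-by-category counts.
#'
#' @param data Data.frame with a `region` column.
#' @param variable Column to compare across regions.
#' @return `shed_comparison`, with `gate` attached for quantitative
#'   variables.
#' @export
compare_regions <- function(data, variable) {
  x <- data[[variable]]
  if (is.numeric(x)) {
    gate <- normality_gate(x, data$region)
    res <- if (gate$decision == "normal") {
      anova_tukey(x, data$region)
    } else {
      kruskal_dunn(x, data$region)
    }
    res$gate <- gate
    res$variable <- variable
    res
  } else {
    counts <- table(data$region, x)
    res <- fisher_battery(counts)
    res$variable <- variable
    res
  }
}
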