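#' Shapiro-Wilk normality gate
#'
#' A data series is treated as Gaussian when the Shapiro-Wilk p-value is at
#' or above the gate alpha. Degenerate (constant) series cannot be tested and
#' are flagged non-Gaussian.
#'
#' @param x numeric series, n >= 3.
#' @param gate_alpha gate level (default 0.05).
#' @return logical: `TRUE` when the series passes the gate.
#' @export
shapiro_gate <- function(x, gate_alpha = 0.05) {
  if (length(x) < 3) stop("normality gate needs n >= 3")
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
  p >= gate_alpha
}

#' Paired pre/post comparison with a normality gate
#'
#' Uses the paired t-test when both series pass the Shapiro-Wilk gate, and
#' the Wilcoxon matched-pairs signed-rank test otherwise (zero differences
#' discarded; exact p for small n without ties, else normal approximation
#' with continuity correction, as implemented by [stats::wilcox.test()]).
#' If every difference is zero, the comparison is degenerate and reported as
#' non-significant (p = 1).
#'
#' @param pre,post paired numeric series of equal length (same realization
#'   order).
#' @param gate_alpha Shapiro-Wilk gate level (default 0.05).
#' @return list with `test` ("paired t" or "wilcoxon"), `statistic`,
#'   `p_value`, `gaussian` (logical pair gate result).
#' @export
paired_compare <- function(pre, post, gate_alpha = 0.05) {
  stopifnot(length(pre) == length(post))
  gaussian <- shapiro_gate(pre, gate_alpha) && shapiro_gate(post, gate_alpha)
  if (all(post == pre)) {
    return(list(test = "wilcoxon", statistic = NA_real_, p_value = 1,
                gaussian = gaussian))
  }
  # a constant non-zero difference (common for integer-valued features such
  # as percentiles) degenerates the t statistic; the sign-rank test is exact
  if (stats::sd(post - pre) == 0) gaussian <- FALSE
  if (gaussian) {
    ht <- stats::t.test(post, pre, paired = TRUE)
    list(test = "paired t", statistic = unname(ht$statistic),
         p_value = ht$p.value, gaussian = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE))
    list(test = "wilcoxon", statistic = unname(ht$statistic),
         p_value = ht$p.value, gaussian = FALSE)
  }
}

#' Dunn's multiple-comparisons test
#'
#' Pairwise z tests on mean ranks following a Kruskal-Wallis comparison,
#' with the usual tie correction. Unadjusted two-sided p-values by default;
#' any [stats::p.adjust()] method may be requested.
#'
#' @param values numeric vector of observations.
#' @param groups factor/character of group membership, same length.
#' @param p_adjust adjustment method passed to [stats::p.adjust()]
#'   (default "none").
#' @return data.frame with columns `pair`, `z`, `p_value`.
#' @export
dunn_test <- function(values, groups, p_adjust = "none") {
  groups <- as.factor(groups)
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
    (mean_ranks[pr[1]] - mean_ranks[pr[2]]) / se
  })
  p <- stats::p.adjust(2 * stats::pnorm(-abs(z)), method = p_adjust)
  data.frame(
    pair = paste(pairs[1, ], pairs[2, ], sep = "-"),
    z = as.numeric(z), p_value = as.numeric(p),
    stringsAsFactors = FALSE
  )
}

#' Three-group comparison with a normality gate and post-hoc tests
#'
#' One-way ANOVA followed by Tukey's multiple comparisons when all three
#' series pass the Shapiro-Wilk gate; Kruskal-Wallis followed by Dunn's
#' multiple comparisons otherwise. Returns the omnibus p and all three
#' pairwise p-values.
#'
#' @param l,m,h numeric series for the light, moderate and heavy groups
#'   (n >= 3 each).
#' @param gate_alpha Shapiro-Wilk gate level (default 0.05).
#' @param dunn_adjust p-adjustment for Dunn's pairwise p-values
#'   (default "none").
#' @return list with `method` ("anova+tukey" or "kruskal+dunn"), `omnibus_p`,
#'   `pairwise` (named numeric `L-M`, `L-H`, `M-H`), `gaussian`.
#' @export
group_compare <- function(l, m, h, gate_alpha = 0.05, dunn_adjust = "none") {
  if (any(lengths(list(l, m, h)) < 3)) {
    stop("group comparison needs three series with n >= 3")
  }
  gaussian <- shapiro_gate(l, gate_alpha) && shapiro_gate(m, gate_alpha) &&
    shapiro_gate(h, gate_alpha)
  values <- c(l, m, h)
  groups <- factor(rep(c("L", "M", "H"), c(length(l), length(m), length(h))),
                   levels = c("L", "M", "H"))
  if (gaussian) {
    fit <- stats::aov(values ~ groups)
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$groups
    # rownames are like "M-L", "H-L", "H-M"
    get_p <- function(a, b) {
      i <- match(paste(a, b, sep = "-"), rownames(tk))
      if (is.na(i)) i <- match(paste(b, a, sep = "-"), rownames(tk))
      tk[i, "p adj"]
    }
    pairwise <- c("L-M" = get_p("L", "M"), "L-H" = get_p("L", "H"),
                  "M-H" = get_p("M", "H"))
    list(method = "anova+tukey", omnibus_p = omnibus, pairwise = pairwise,
         gaussian = TRUE)
  } else {
    kw <- stats::kruskal.test(values, groups)
    dn <- dunn_test(values, groups, p_adjust = dunn_adjust)
    get_p <- function(a, b) {
      i <- match(paste(a, b, sep = "-"), dn$pair)
      if (is.na(i)) i <- match(paste(b, a, sep = "-"), dn$pair)
      dn$p_value[i]
    }
    pairwise <- c("L-M" = get_p("L", "M"), "L-H" = get_p("L", "H"),
                  "M-H" = get_p("M", "H"))
    list(method = "kruskal+dunn", omnibus_p = kw$p.value, pairwise = pairwise,
         gaussian = FALSE)
  }
}

#' Classify the pairwise-difference pattern
#'
#' Patterns of post-hoc group differences:
#' * `III`: all three pairs differ (groups L, M, H all separate).
#' * `II`: L-H and M-H differ but L-M does not (L and M jointly differ from
#'   H).
#' * `I`: only L-H differs.
#' * `none`: no pair differs.
#' * `other`: any remaining configuration, reported verbatim.
#'
#' @param pairwise named numeric p-values `L-M`, `L-H`, `M-H`.
#' @param alpha significance level (default 0.05).
#' @return one of "none", "I", "II", "III", "other".
#' @export
classify_pattern <- function(pairwise, alpha = 0.05) {
  lm <- pairwise[["L-M"]] < alpha
  lh <- pairwise[["L-H"]] < alpha
  mh <- pairwise[["M-H"]] < alpha
  if (lm && lh && mh) return("III")
  if (!lm && lh && mh) return("II")
  if (!lm && lh && !mh) return("I")
  if (!lm && !lh && !mh) return("none")
  "other"
}

feature_columns <- function(features) {
  grep("^ROI[0-9]+_", names(features), value = TRUE)
}

#' Pre/post screen over all feature columns
#'
#' For every feature column (texture and conventional) and every group, the
#' pre- and post-exercise series are paired by realization (rider x horse)
#' and compared with [paired_compare()]. A feature is carried forward only
#' when it differs significantly in all three groups simultaneously.
#'
#' @param features wide feature table from [extract_all_features()] with
#'   metadata columns `rider_id`, `horse_id`, `timepoint` ("pre"/"post"),
#'   `group`.
#' @param alpha significance level (default 0.05).
#' @param gate_alpha Shapiro-Wilk gate level (default 0.05).
#' @return data.frame, one row per feature column: per-group p-values and
#'   test names, and logical `carried`.
#' @export
prepost_screen <- function(features, alpha = 0.05, gate_alpha = 0.05) {
  stopifnot(all(c("rider_id", "horse_id", "timepoint", "group") %in%
                  names(features)))
  cols <- feature_columns(features)
  pre <- features[features$timepoint == "pre", ]
  post <- features[features$timepoint == "post", ]
  key <- function(d) paste(d$rider_id, d$horse_id)
  post <- post[match(key(pre), key(post)), ]
  stopifnot(!anyNA(post$rider_id))
  groups <- c("L", "M", "H")
  rows <- lapply(cols, function(cl) {
    res <- lapply(groups, function(g) {
      sel <- pre$group == g
      paired_compare(pre[[cl]][sel], post[[cl]][sel], gate_alpha)
    })
    p <- vapply(res, `[[`, numeric(1), "p_value")
    data.frame(
      feature_col = cl,
      p_L = p[1], p_M = p[2], p_H = p[3],
      test_L = res[[1]]$test, test_M = res[[2]]$test, test_H = res[[3]]$test,
      carried = all(p < alpha),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$p_fdr_max <- stats::p.adjust(pmax(out$p_L, out$p_M, out$p_H), "BH")
  rownames(out) <- NULL
  out
}

#' Group comparisons for carried-forward features
#'
#' For each carried-forward feature, the post-exercise series of the three
#' groups are compared with [group_compare()] and the resulting pairwise
#' p-values classified into difference pattern I/II/III.
#'
#' @param features wide feature table (see [prepost_screen()]).
#' @param screen output of [prepost_screen()].
#' @param alpha significance level (default 0.05).
#' @param gate_alpha Shapiro-Wilk gate level.
#' @param dunn_adjust p-adjustment for Dunn's test (default "none").
#' @return data.frame, one row per carried feature: method, omnibus and
#'   pairwise p-values, `pattern`.
#' @export
group_screen <- function(features, screen, alpha = 0.05, gate_alpha = 0.05,
                         dunn_adjust = "none") {
  post <- features[features$timepoint == "post", ]
  cols <- screen$feature_col[screen$carried]
  rows <- lapply(cols, function(cl) {
    gc <- group_compare(
      post[[cl]][post$group == "L"],
      post[[cl]][post$group == "M"],
      post[[cl]][post$group == "H"],
      gate_alpha, dunn_adjust
    )
    data.frame(
      feature_col = cl, method = gc$method, omnibus_p = gc$omnibus_p,
      p_LM = gc$pairwise[["L-M"]], p_LH = gc$pairwise[["L-H"]],
      p_MH = gc$pairwise[["M-H"]],
      pattern = classify_pattern(gc$pairwise, alpha),
      stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    feature_col = character(), method = character(), omnibus_p = numeric(),
    p_LM = numeric(), p_LH = numeric(), p_MH = numeric(),
    pattern = character(), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Run the full two-stage statistical screen
#'
#' Stage one: paired pre/post comparison per group with the
#' all-three-groups-simultaneously selection rule. Stage two: three-group
#' post-exercise comparison with post-hoc pattern classification for the
#' carried-forward features.
#'
#' @inheritParams prepost_screen
#' @param dunn_adjust p-adjustment for Dunn's test.
#' @return list with `screen`, `groups` (stage-two results), `grid`
#'   (see [build_significance_grid()]).
#' @export
analyze_study <- function(features, alpha = 0.05, gate_alpha = 0.05,
                          dunn_adjust = "none") {
  screen <- prepost_screen(features, alpha, gate_alpha)
  groups <- group_screen(features, screen, alpha, gate_alpha, dunn_adjust)
  grid <- build_significance_grid(screen, groups)
  list(screen = screen, groups = groups, grid = grid)
}

#' Machine-readable significance grid
#'
#' The grid is the machine twin of the study's significance figures: one row
#' per feature column with its ROI, component (NA for conventional thermal
#' features), feature name, family (conventional/HS/GLRLM/GLCM), the
#' carried-forward flag and the group-difference pattern.
#'
#' @param screen output of [prepost_screen()].
#' @param groups output of [group_screen()].
#' @return data.frame grid.
#' @export
build_significance_grid <- function(screen, groups) {
  parts <- strsplit(screen$feature_col, "_")
  roi <- vapply(parts, `[[`, character(1), 1)
  comp <- vapply(parts, function(p) if (length(p) == 3) p[[2]] else NA_character_,
                 character(1))
  feat <- vapply(parts, function(p) p[[length(p)]], character(1))
  fams <- texture_feature_names()
  family <- ifelse(is.na(comp), "conventional",
    ifelse(feat %in% fams$hs, "HS",
      ifelse(feat %in% fams$glrlm, "GLRLM", "GLCM")
    )
  )
  pattern <- groups$pattern[match(screen$feature_col, groups$feature_col)]
  pattern[is.na(pattern)] <- ""
  data.frame(
    feature_col = screen$feature_col, roi = roi, component = comp,
    feature = feat, family = family, carried = screen$carried,
    pattern = pattern, stringsAsFactors = FALSE
  )
}

#' Plot the significance grid as a heat-grid
#'
#' A tile plot of feature (x) by ROI-and-component (y), filled by the
#' carried-forward flag and annotated with the difference pattern. Requires
#' ggplot2.
#'
#' @param grid output of [build_significance_grid()].
#' @return a ggplot object.
#' @export
plot_significance_grid <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_significance_grid requires ggplot2")
  }
  g <- grid[!is.na(grid$component), ]
  g$row <- paste(g$roi, g$component)
  ggplot2::ggplot(g, ggplot2::aes(
    x = factor(.data$feature, levels = unique(.data$feature)),
    y = .data$row, fill = .data$carried
  )) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$pattern), size = 2.5) +
    ggplot2::scale_fill_manual(values = c("FALSE" = "white", "TRUE" = "tomato")) +
    ggplot2::labs(x = "feature", y = "ROI / component", fill = "pre/post\nselected") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
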