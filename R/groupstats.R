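#' Per-retina means of per-image values
#'
#' Averages each metric over the 2-4 images of a retina to give the retinal
#' mean, the unit of all group comparisons. A retina carrying conflicting
#' genotype labels across its images is an upstream bookkeeping error and
#' is rejected.
#'
#' @param per_image data.frame with columns `image_id`, `retina_id`,
#'   `genotype`, `value` and optionally `metric`.
#' @return group table `(retina_id, genotype, metric, value)`.
#' @export
retina_means <- function(per_image) {
  need <- c("image_id", "retina_id", "genotype", "value")
  stopifnot(all(need %in% names(per_image)))
  if (!"metric" %in% names(per_image)) per_image$metric <- "value"
  chk <- unique(per_image[, c("retina_id", "genotype")])
  dupg <- chk$retina_id[duplicated(chk$retina_id)]
  if (length(dupg) > 0)
    stop("conflicting genotype labels for retina: ",
         paste(unique(dupg), collapse = ", "))
  agg <- stats::aggregate(value ~ retina_id + genotype + metric, per_image,
                          mean)
  agg[order(agg$metric, agg$genotype, agg$retina_id),
      c("retina_id", "genotype", "metric", "value")]
}

#' One-way ANOVA with Tukey HSD post-hoc tests across genotypes
#'
#' Retinal means are compared across genotypes by one-way ANOVA; all
#' pairwise genotype contrasts are then tested with Tukey's HSD
#' (studentized-range with the Tukey-Kramer adjustment for unequal retina
#' counts).
#'
#' @param table group table `(retina_id, genotype, metric, value)` holding
#'   one metric.
#' @return list with `anova` (data.frame: F, df, p) and `tukey`
#'   (data.frame: group pair, difference, adjusted p).
#' @export
anova_tukey <- function(table) {
  counts <- base::table(table$genotype)
  bad <- names(counts)[counts < 2]
  if (length(counts) < 2 || length(bad) > 0)
    stop("need >= 2 genotypes with >= 2 retinas each",
         if (length(bad) > 0) paste0("; degenerate: ",
                                     paste(bad, collapse = ", ")) else "")
  df <- data.frame(value = table$value,
                   genotype = factor(table$genotype))
  fit <- stats::aov(value ~ genotype, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$genotype
  list(
    anova = data.frame(test_name = "one-way ANOVA",
                       statistic = an$`F value`[1],
                       df1 = an$Df[1], df2 = an$Df[2],
                       p_raw = an$`Pr(>F)`[1],
                       stringsAsFactors = FALSE),
    tukey = data.frame(comparison = rownames(tk),
                       diff = tk[, "diff"],
                       lwr = tk[, "lwr"], upr = tk[, "upr"],
                       p_adjusted = tk[, "p adj"],
                       adjustment = "tukey",
                       row.names = NULL, stringsAsFactors = FALSE)
  )
}

#' Two-way ANOVA for genotype x threshold-level designs
#'
#' Main effects and interaction for the percent-area measurements taken at
#' several threshold levels per retina: `value ~ genotype * level`.
#'
#' @param table data.frame with columns `genotype`, `level`, `value` (one
#'   row per retina per level; complete layout required).
#' @return data.frame with one row per term: `term`, `df`, `statistic`
#'   (F), `p_raw`.
#' @export
two_way_anova <- function(table) {
  stopifnot(all(c("genotype", "level", "value") %in% names(table)))
  df <- data.frame(value = table$value,
                   genotype = factor(table$genotype),
                   level = factor(table$level))
  cells <- base::table(df$genotype, df$level)
  if (any(cells == 0))
    stop("incomplete two-factor layout: empty genotype x level cells")
  fit <- stats::aov(value ~ genotype * level, data = df)
  an <- summary(fit)[[1]]
  terms <- trimws(rownames(an))
  data.frame(term = terms, df = an$Df,
             sum_sq = an$`Sum Sq`,
             statistic = an$`F value`, p_raw = an$`Pr(>F)`,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample Student's t-test on retinal means
#'
#' For experiments comparing exactly two genotypes. Equal-variance
#' Student's t by default; `welch = TRUE` relaxes that.
#'
#' @param table group table with exactly two genotypes, each with >= 2
#'   retinas.
#' @param welch use the Welch unequal-variance test.
#' @return data.frame: groups, n per group, t statistic, df, p.
#' @export
t_test_groups <- function(table, welch = FALSE) {
  groups <- sort(unique(table$genotype))
  if (length(groups) != 2)
    stop("t_test_groups requires exactly 2 genotypes, got ",
         length(groups))
  v1 <- table$value[table$genotype == groups[1]]
  v2 <- table$value[table$genotype == groups[2]]
  if (length(v1) < 2 || length(v2) < 2) stop("each group needs >= 2 retinas")
  tt <- stats::t.test(v1, v2, var.equal = !welch)
  data.frame(test_name = if (welch) "Welch t-test" else "Student t-test",
             group1 = groups[1], group2 = groups[2],
             n1 = length(v1), n2 = length(v2),
             statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_raw = tt$p.value, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values (monotone, capped at 1), as
#' applied to the pairwise Wilcoxon comparisons of Elo scores.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}
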