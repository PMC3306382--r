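# Plate-level assay computations: centrifugal adhesion fractions,
# delta-delta-Ct qPCR fold changes, and group summaries with the usual
# significance-star annotation.

#' Adherent cell fraction from a centrifugal adhesion assay
#'
#' Fraction of cells remaining attached after centrifugation, from
#' fluorescence readings taken before (`pre`) and after (`post`) the
#' spin: `(post - blank) / (pre - blank)`.  Scale-invariant: multiplying
#' all readings by a constant leaves the fraction unchanged.  Values are
#' clipped below at 0; fractions above 1.05 (post exceeding pre beyond
#' plausible reader noise) are flagged with a warning.
#'
#' @param pre,post fluorescence before/after the spin, arbitrary units
#'   (vectorized).
#' @param blank optional blank-well reading subtracted from both (0 when
#'   no blank was measured).
#' @return numeric vector of adherent fractions.
#' @export
adherent_fraction <- function(pre, post, blank = 0) {
  if (any(blank < 0)) stop("blank must be non-negative")
  if (any(pre <= blank))
    stop("pre-spin fluorescence must exceed the blank")
  frac <- pmax((post - blank) / (pre - blank), 0)
  if (any(frac > 1.05))
    warning(sum(frac > 1.05), " adherent fraction(s) exceed 1.05; ",
            "check well readings")
  frac
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = Ct(gene) - Ct(reference gene)`; `ddCt` references
#' each gene's dCt to the mean dCt of `reference_group`; relative
#' expression is `2^-ddCt`.  Group means and standard errors are computed
#' on the per-sample fold changes (so the reported mean +- SEM is on the
#' fold-change scale); computing them on ddCt and transforming afterwards
#' is available via `sem_on = "ddct"`.
#'
#' @param records data frame with columns `sample_id`, `group`, `gene`,
#'   `ct`; every sample must include a `reference_gene` row.
#' @param reference_group group label the fold changes are relative to
#'   (its own mean fold change is exactly 1).
#' @param reference_gene endogenous control gene (default `"GAPDH"`).
#' @param sem_on `"fold"` (default) or `"ddct"`.
#' @return data frame with `gene`, `group`, `fold_change`, `sem`, `n`.
#' @export
ddct_fold_change <- function(records, reference_group,
                             reference_gene = "GAPDH",
                             sem_on = c("fold", "ddct")) {
  sem_on <- match.arg(sem_on)
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(records)))
  if (any(records$ct <= 0)) stop("Ct values must be positive")
  if (!reference_group %in% records$group)
    stop("reference group '", reference_group, "' not present")
  ref <- records[records$gene == reference_gene, ]
  missing_ref <- setdiff(unique(records$sample_id), unique(ref$sample_id))
  if (length(missing_ref) > 0L)
    stop("sample(s) missing a ", reference_gene, " measurement: ",
         paste(missing_ref, collapse = ", "))
  ref_ct <- stats::setNames(ref$ct, ref$sample_id)
  genes <- records[records$gene != reference_gene, ]
  genes$dct <- genes$ct - ref_ct[as.character(genes$sample_id)]
  out <- list()
  for (g in unique(genes$gene)) {
    sub <- genes[genes$gene == g, ]
    ref_dct <- mean(sub$dct[sub$group == reference_group])
    if (is.nan(ref_dct))
      stop("reference group has no measurements for gene ", g)
    sub$fold <- 2^(-(sub$dct - ref_dct))
    for (grp in unique(sub$group)) {
      v <- sub[sub$group == grp, ]
      n <- nrow(v)
      if (sem_on == "fold") {
        fc <- mean(v$fold)
        sem <- if (n > 1) stats::sd(v$fold) / sqrt(n) else 0
      } else {
        ddct <- v$dct - ref_dct
        fc <- 2^(-mean(ddct))
        sem <- if (n > 1)
          fc * log(2) * stats::sd(ddct) / sqrt(n) else 0
      }
      out[[length(out) + 1L]] <- data.frame(gene = g, group = grp,
                                            fold_change = fc, sem = sem,
                                            n = n)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Significance stars at the 0.05 / 0.01 / 0.001 levels
#'
#' @param p p-value(s).
#' @return character vector: `"***"` p<0.001, `"**"` p<0.01, `"*"` p<0.05,
#'   `""` otherwise.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Compare groups and report mean +- SEM with significance stars
#'
#' One-factor design: Student's t-test for two groups, one-way ANOVA for
#' more.  Two-factor design: two-way ANOVA with interaction, reporting
#' both main effects and the interaction (as used to test a cell-type x
#' treatment interaction).
#'
#' @param values numeric response.
#' @param group group labels (one-factor), ignored in two-factor mode.
#' @param design `"one-factor"` or `"two-factor"`.
#' @param factors data frame with two factor columns (two-factor mode).
#' @param var_equal passed to [stats::t.test()] (classic Student's test by
#'   default).
#' @return list with `summary` (group, mean, sem, n), `test`, `p_value`
#'   (named vector in two-factor mode), `stars`.
#' @export
group_compare <- function(values, group = NULL,
                          design = c("one-factor", "two-factor"),
                          factors = NULL, var_equal = TRUE) {
  design <- match.arg(design)
  if (design == "one-factor") {
    stopifnot(!is.null(group), length(values) == length(group))
    group <- as.factor(group)
    n_by <- tapply(values, group, length)
    if (any(n_by < 2))
      stop("every group needs at least 2 values; offending group(s): ",
           paste(names(n_by)[n_by < 2], collapse = ", "))
    summ <- data.frame(
      group = levels(group),
      mean = as.vector(tapply(values, group, mean)),
      sem = as.vector(tapply(values, group,
                             function(v) stats::sd(v) / sqrt(length(v)))),
      n = as.vector(n_by))
    if (nlevels(group) == 2L) {
      tt <- stats::t.test(values ~ group, var.equal = var_equal)
      p <- tt$p.value
      test <- "t-test"
    } else {
      fit <- stats::aov(values ~ group)
      p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
      test <- "one-way ANOVA"
    }
    list(summary = summ, test = test, p_value = p,
         stars = significance_stars(p))
  } else {
    stopifnot(!is.null(factors), ncol(factors) >= 2L,
              nrow(factors) == length(values))
    f1 <- as.factor(factors[[1L]])
    f2 <- as.factor(factors[[2L]])
    cell <- interaction(f1, f2, drop = TRUE)
    if (any(tapply(values, cell, length) < 2))
      stop("every factor combination needs at least 2 values")
    fit <- stats::aov(values ~ f1 * f2)
    tab <- summary(fit)[[1L]]
    p <- stats::setNames(tab[["Pr(>F)"]][1:3],
                         c(names(factors)[1L], names(factors)[2L],
                           "interaction"))
    summ <- data.frame(
      group = levels(cell),
      mean = as.vector(tapply(values, cell, mean)),
      sem = as.vector(tapply(values, cell,
                             function(v) stats::sd(v) / sqrt(length(v)))),
      n = as.vector(tapply(values, cell, length)))
    list(summary = summ, test = "two-way ANOVA", p_value = p,
         stars = significance_stars(p))
  }
}
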