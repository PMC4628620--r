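#' Select index SNPs, one per locus
#'
#' From a raw GWAS catalog (columns `id`, `source_trait`, `locus`, `pvalue`)
#' keeps, within each locus, the SNP with the lowest discovery P-value
#' (ties broken by lexicographically smallest id).  SNPs absent from
#' `available` (e.g. not present in the dosage matrix) are dropped first,
#' with a message per dropped id.
#'
#' @param catalog data.frame of raw catalog rows.
#' @param available optional character vector of obtainable SNP ids.
#' @return the filtered catalog (class `snp_catalog`), one row per locus.
#' @export
select_index_snps <- function(catalog, available = NULL) {
  stopifnot(is.data.frame(catalog))
  need <- c("id", "source_trait", "locus", "pvalue")
  miss <- setdiff(need, names(catalog))
  if (length(miss)) stop("catalog lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(catalog)) stop("empty SNP catalog")
  bad <- setdiff(unique(catalog$source_trait), ECG_TRAITS)
  if (length(bad))
    stop("unrecognized source trait(s) in catalog: ", paste(bad, collapse = ", "))
  if (!is.null(available)) {
    gone <- !(catalog$id %in% available)
    if (any(gone))
      message("dropped (unavailable): ", paste(catalog$id[gone], collapse = ", "))
    catalog <- catalog[!gone, , drop = FALSE]
    if (!nrow(catalog)) stop("no catalog SNPs available in the dosage data")
  }
  catalog <- catalog[order(catalog$locus, catalog$pvalue, catalog$id), ]
  keep <- !duplicated(catalog$locus)
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_catalog", "data.frame")
  out
}

#' SNP sets entering models 1, 2 and 3 for a trait
#'
#' Model 1 carries no SNPs (covariates are residualized out beforehand, so its
#' design is the intercept alone).  Model 2 adds the trait-specific SNPs:
#' the catalog SNPs discovered for that trait, except that the LVH proxies
#' borrow the QRS set (QRS is a component of each product and the proxies have
#' almost no dedicated genome-wide-significant loci) -- SL and CV use the QRS
#' SNPs, 12LS uses the QRS SNPs plus its own.  Model 3 adds every catalog SNP.
#'
#' @param trait one of `QRS, QT, PR, SL, CV, 12LS`.
#' @param catalog a selected [select_index_snps()] catalog.
#' @return list with character vectors `m1` (empty), `m2`, `m3`.
#' @export
build_model_specs <- function(trait, catalog) {
  if (!trait %in% ECG_TRAITS)
    stop("unknown trait '", trait, "'")
  stopifnot(is.data.frame(catalog))
  if (!nrow(catalog)) stop("empty SNP catalog")
  by_trait <- split(catalog$id, catalog$source_trait)
  own <- switch(trait,
    QRS = by_trait[["QRS"]],
    QT  = by_trait[["QT"]],
    PR  = by_trait[["PR"]],
    SL  = by_trait[["QRS"]],
    CV  = by_trait[["QRS"]],
    `12LS` = c(by_trait[["QRS"]], by_trait[["12LS"]]))
  own <- unique(own)
  if (!length(own))
    stop("no catalog SNPs for trait '", trait,
         "' and no fallback rule applies")
  list(m1 = character(0), m2 = own, m3 = unique(catalog$id))
}

#' Proportion of heritability explained
#'
#' \eqn{100\,(h^2_{before} - h^2_{after}) / h^2_{before}}, in percent.
#' Negative values (heritability increasing when SNPs are conditioned on) are
#' legitimate and reported as such.
#'
#' @param h2_before heritability of the less-conditioned model (> 0).
#' @param h2_after heritability after conditioning.
#' @return percentage (may be negative).
#' @export
proportion_explained <- function(h2_before, h2_after) {
  if (any(is.na(h2_before)) || any(h2_before <= 0))
    stop("proportion explained undefined for h2_before <= 0")
  100 * (h2_before - h2_after) / h2_before
}

build_design <- function(ids, snps, dosages) {
  X <- cbind(`(Intercept)` = rep(1, length(ids)))
  rownames(X) <- ids
  if (length(snps)) {
    D <- as.matrix(dosages[ids, snps, drop = FALSE])
    keep <- apply(D, 2, function(col) stats::sd(col) > 0)
    if (!all(keep))
      message("dropping constant dosage column(s): ",
              paste(snps[!keep], collapse = ", "))
    X <- cbind(X, D[, keep, drop = FALSE])
  }
  X
}

#' Fit the three conditioning models for one trait
#'
#' Fits model 1 (intercept only), model 2 (plus trait-specific SNP dosages)
#' and model 3 (plus all catalog SNPs) on the identical complete-case subset
#' of individuals, then assembles the heritability decomposition:
#' per-model \eqn{h^2} (total-variance scale, see [h2_total()]) with SE and
#' the boundary test of \eqn{h^2 = 0}, \eqn{\Delta h^2} between successive
#' models, the proportion of model-1 heritability explained, and nested
#' likelihood-ratio tests (degrees of freedom = number of added SNP columns).
#'
#' @param trait trait name.
#' @param y named numeric vector of analysis trait values (ids as names;
#'   `NA` allowed and dropped).
#' @param kin `kinship_result` or `kinship_eigen`.
#' @param dosages numeric matrix or data.frame of SNP dosages in `[0, 2]`,
#'   rownames = individual ids.
#' @param catalog a [select_index_snps()] catalog.
#' @param se compute h2 standard errors.
#' @return one-row data.frame (class `herit_row`) with attribute `fits`
#'   holding the three `polygenic` objects.
#' @export
run_three_models <- function(trait, y, kin, dosages, catalog, se = TRUE) {
  specs <- build_model_specs(trait, catalog)
  dosages <- as.matrix(dosages)
  ids <- names(y)
  if (is.null(ids)) stop("y must be named by individual id")
  snp_all <- specs$m3
  miss <- setdiff(snp_all, colnames(dosages))
  if (length(miss))
    stop("catalog SNP(s) absent from dosages: ", paste(miss, collapse = ", "))
  ok <- !is.na(y) & ids %in% rownames(dosages)
  ids <- ids[ok]
  complete <- stats::complete.cases(dosages[ids, snp_all, drop = FALSE])
  ids <- ids[complete]
  if (length(ids) < 10) stop("too few complete cases for trait ", trait)

  eig <- as_kinship_eigen(if (inherits(kin, "kinship_eigen")) kin else
    kinship_eigen(kin, ids), ids)
  ids <- eig$ids
  yy <- as.numeric(y[ids])

  # ML fits carry the likelihoods (boundary test, nested LRTs, SEs); REML
  # refits provide the variance components free of fixed-effect dof bias.
  fits <- lapply(list(specs$m1, specs$m2, specs$m3), function(s)
    polygenic_fit(yy, build_design(ids, s, dosages), eig, se = se))
  refits <- lapply(fits, function(f)
    polygenic_fit(f$y, f$X, eig, se = FALSE, reml = TRUE))
  if (!all(vapply(fits, function(f) f$n, 0L) == length(ids)))
    stop("sample-set drift between models")

  h2 <- vapply(refits, h2_total, numeric(1))
  lrt12 <- lrt_nested(fits[[2]], fits[[1]])
  lrt23 <- lrt_nested(fits[[3]], fits[[2]])
  row <- data.frame(
    trait = trait, n = length(ids),
    h2_m1 = h2[1], se_m1 = fits[[1]]$h2_se, p_m1 = fits[[1]]$p_h2,
    h2_m2 = h2[2], se_m2 = fits[[2]]$h2_se, p_m2 = fits[[2]]$p_h2,
    dh2_12 = h2[1] - h2[2], p_lrt_12 = lrt12$p,
    n_snps_m2 = length(specs$m2),
    h2_m3 = h2[3], se_m3 = fits[[3]]$h2_se, p_m3 = fits[[3]]$p_h2,
    dh2_23 = h2[2] - h2[3], p_lrt_23 = lrt23$p,
    n_snps_m3 = length(specs$m3),
    prop_explained_12 = proportion_explained(h2[1], h2[2]),
    prop_explained_23 = 100 * (h2[2] - h2[3]) / h2[1],
    stringsAsFactors = FALSE)
  attr(row, "fits") <- fits
  attr(row, "refits") <- refits
  class(row) <- c("herit_row", "data.frame")
  row
}

#' Cross-phenotype SNP-set decomposition
#'
#' For each foreign SNP set (catalog source traits other than the trait's own
#' model-2 set), refits model 2 plus that set alone and reports the
#' additional proportion of model-1 heritability explained,
#' \eqn{100 (h^2_{m2} - h^2_{m2+set}) / h^2_{m1}}, with the nested LRT
#' p-value.  SNPs already in the model-2 set are removed from the foreign set
#' with a warning; sets left empty are omitted.
#'
#' @inheritParams run_three_models
#' @return data.frame with one row per foreign SNP set.
#' @export
cross_phenotype_decomposition <- function(trait, y, kin, dosages, catalog,
                                          se = FALSE) {
  specs <- build_model_specs(trait, catalog)
  base <- run_three_models(trait, y, kin, dosages, catalog, se = se)
  fits <- attr(base, "fits")
  refits <- attr(base, "refits")
  eig <- fits[[1]]$eig
  ids <- fits[[1]]$ids
  yy <- fits[[1]]$y
  own_source <- switch(trait, SL = , CV = "QRS", `12LS` = c("QRS", "12LS"),
                       trait)
  foreign_traits <- setdiff(unique(catalog$source_trait), own_source)
  rows <- list()
  for (ft in foreign_traits) {
    set <- catalog$id[catalog$source_trait == ft]
    overlap <- intersect(set, specs$m2)
    if (length(overlap)) {
      warning("SNP(s) ", paste(overlap, collapse = ", "),
              " already in the model-2 set; deduplicated")
      set <- setdiff(set, specs$m2)
    }
    if (!length(set)) next
    Xp <- build_design(ids, c(specs$m2, set), dosages)
    fit_plus <- polygenic_fit(yy, Xp, eig, se = se)
    refit_plus <- polygenic_fit(yy, Xp, eig, se = FALSE, reml = TRUE)
    lt <- lrt_nested(fit_plus, fits[[2]])
    rows[[ft]] <- data.frame(
      trait = trait, snp_set = ft, n_snps = length(set),
      additional_prop = 100 * (h2_total(refits[[2]]) - h2_total(refit_plus)) /
        h2_total(refits[[1]]),
      p_lrt = lt$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "base") <- base
  out
}

#' Heritability report over several traits
#'
#' Runs [run_three_models()] per trait and binds the rows into a report
#' mirroring the usual three-model heritability table.
#'
#' @param traits_table data.frame of analysis-ready traits: `id` column plus
#'   one column per trait (output of [prepare_traits()]).
#' @param traits which traits to analyze (default: every trait column found).
#' @inheritParams run_three_models
#' @return data.frame of class `herit_report`.
#' @export
heritability_report <- function(traits_table, kin, dosages, catalog,
                                traits = NULL, se = TRUE) {
  stopifnot(is.data.frame(traits_table), "id" %in% names(traits_table))
  if (is.null(traits)) traits <- intersect(ECG_TRAITS, names(traits_table))
  rows <- lapply(traits, function(tr) {
    y <- stats::setNames(traits_table[[tr]], traits_table$id)
    r <- run_three_models(tr, y, kin, dosages, catalog, se = se)
    attr(r, "fits") <- NULL
    r
  })
  out <- do.call(rbind, rows)
  class(out) <- c("herit_report", "data.frame")
  out
}

#' @export
print.herit_report <- function(x, ...) {
  cat("Three-model heritability report\n")
  show <- data.frame(
    trait = x$trait, n = x$n,
    `h2 m1` = sprintf("%.2f (%.2f)", x$h2_m1, x$se_m1),
    `h2 m2` = sprintf("%.2f (%.2f)", x$h2_m2, x$se_m2),
    `dh2 1-2` = sprintf("%.2f", x$dh2_12),
    `expl %` = sprintf("%.1f", x$prop_explained_12),
    `h2 m3` = sprintf("%.2f (%.2f)", x$h2_m3, x$se_m3),
    `dh2 2-3` = sprintf("%.2f", x$dh2_23),
    check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}
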