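# Feature assembly for the two preeclampsia classifiers.
#
# Early-onset (EPE) feature vector: 5 clinical encodings + the 8-gene
# promoter-coverage profile (FOSL2, CAMKK2, CCND1, ITPR1, PRKACB, WNT7B,
# CACNB2, NRF1) = 13 features. Late-onset (LPE): the same 5 clinical
# encodings + the FLT3LG/EGF promoter-coverage ratio = 6 features.

clinical_feature_names <- function() {
  c("age_mom", "bmi_mom", "parity", "pmh", "ivf")
}

#' Clinical feature encodings
#'
#' Maternal age and BMI are expressed as multiples of the per-dataset
#' control median (mirroring the cfDNA MoM convention); parity is the
#' birth count; `pmh` is the 0-4 sum of the four past-medical-history
#' flags (chronic hypertension, prior PE, SLE, antiphospholipid
#' syndrome); `ivf` is 1 for IVF conception, 0 for natural.
#'
#' @param clinical Clinical table with columns sample_id, dataset, label,
#'   age, bmi, parity, pmh_htn, pmh_pe, pmh_sle, pmh_aps, conception.
#' @param control_medians Optional precomputed list(age =, bmi =) of named
#'   per-dataset control medians; computed from `clinical` when NULL (the
#'   usual case — supply them when encoding new samples against an
#'   existing reference cohort).
#' @return data.frame: sample_id, dataset, label, age_mom, bmi_mom, parity,
#'   pmh, ivf.
#' @export
clinical_features <- function(clinical, control_medians = NULL) {
  req <- c("sample_id", "dataset", "label", "age", "bmi", "parity",
           "pmh_htn", "pmh_pe", "pmh_sle", "pmh_aps", "conception")
  miss <- setdiff(req, names(clinical))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- !stats::complete.cases(clinical[req]) | clinical$age <= 0 |
    clinical$bmi <= 0
  if (any(bad)) {
    message(sum(bad), " sample(s) dropped for incomplete clinical records")
    clinical <- clinical[!bad, , drop = FALSE]
  }
  if (is.null(control_medians)) {
    ds <- unique(clinical$dataset)
    med_of <- function(col) vapply(ds, function(d) {
      v <- clinical[[col]][clinical$dataset == d &
                             clinical$label == "control"]
      if (!length(v)) stop("dataset with zero control samples: ", d)
      stats::median(v)
    }, numeric(1))
    control_medians <- list(age = med_of("age"), bmi = med_of("bmi"))
  }
  data.frame(
    sample_id = clinical$sample_id,
    dataset = clinical$dataset,
    label = clinical$label,
    age_mom = clinical$age / unname(control_medians$age[clinical$dataset]),
    bmi_mom = clinical$bmi / unname(control_medians$bmi[clinical$dataset]),
    parity = clinical$parity,
    pmh = clinical$pmh_htn + clinical$pmh_pe + clinical$pmh_sle +
      clinical$pmh_aps,
    ivf = as.integer(clinical$conception == "IVF"),
    stringsAsFactors = FALSE
  )
}

resolve_genes <- function(mom_cols, gene_map, genes) {
  miss <- setdiff(genes, names(gene_map))
  if (length(miss)) stop("gene(s) not bound to promoters: ",
                         paste(miss, collapse = ", "))
  ids <- gene_map[genes]
  dup <- genes[duplicated(ids) | duplicated(ids, fromLast = TRUE)]
  multi <- vapply(ids, function(id) sum(mom_cols == id), integer(1))
  if (any(multi != 1)) {
    stop("gene(s) missing or multi-mapped in the coverage matrix: ",
         paste(genes[multi != 1], collapse = ", "))
  }
  if (length(dup)) stop("gene(s) mapped to a shared promoter: ",
                        paste(unique(dup), collapse = ", "))
  ids
}

#' Early-onset cfDNA features: the 8-gene promoter MoM profile
#'
#' @param mom A `mom_matrix` (or plain MoM matrix).
#' @param gene_map Named character vector gene symbol -> promoter id.
#' @param genes Profile genes, in fixed order (default the 8 EPE genes).
#' @return samples x 8 matrix of MoM coverages, columns named by gene.
#' @export
epe_cfdna_features <- function(mom, gene_map, genes = epe_profile_genes()) {
  mat <- if (inherits(mom, "mom_matrix")) mom$mom else as.matrix(mom)
  ids <- resolve_genes(colnames(mat), gene_map, genes)
  out <- mat[, ids, drop = FALSE]
  colnames(out) <- genes
  out
}

#' Late-onset cfDNA feature: the FLT3LG/EGF coverage ratio
#'
#' Samples whose denominator (EGF) MoM is 0 or undefined are flagged and
#' excluded (NA), with the exclusion count reported as an attribute.
#'
#' @param mom A `mom_matrix` (or plain MoM matrix).
#' @param gene_map Named character vector gene symbol -> promoter id.
#' @param genes Length-2 vector c(numerator, denominator) gene symbols.
#' @return Named numeric vector `cfdna_ratio` per sample; attribute
#'   `n_excluded` counts undefined samples.
#' @export
lpe_cfdna_feature <- function(mom, gene_map, genes = lpe_profile_genes()) {
  mat <- if (inherits(mom, "mom_matrix")) mom$mom else as.matrix(mom)
  ids <- resolve_genes(colnames(mat), gene_map, genes)
  num <- mat[, ids[1]]
  den <- mat[, ids[2]]
  ratio <- ifelse(!is.na(den) & den > 0 & !is.na(num), num / den, NA_real_)
  n_excl <- sum(is.na(ratio))
  if (n_excl) message(n_excl, " sample(s) with zero/undefined ", genes[2],
                      " coverage excluded from the ratio feature")
  structure(stats::setNames(ratio, rownames(mat)), n_excluded = n_excl)
}

#' Assemble classifier feature tables
#'
#' Joins the clinical encodings with the class-appropriate cfDNA features
#' and freezes the feature schema (13 features for EPE, 6 for LPE; a
#' schema hash is attached for downstream checks). Samples lacking any
#' feature are dropped.
#'
#' @param mom A `mom_matrix`.
#' @param clinical Clinical table.
#' @param gene_map Named gene symbol -> promoter id map.
#' @param class `"EPE"` or `"LPE"`.
#' @param feature_set `"combined"`, `"clinical"` or `"cfdna"`.
#' @return data.frame: sample_id, dataset, label, y (1 = case of `class`,
#'   0 = control; other-class samples dropped), then the feature columns;
#'   attributes `schema` (feature names) and `schema_hash`.
#' @export
build_features <- function(mom, clinical, gene_map, class = c("EPE", "LPE"),
                           feature_set = c("combined", "clinical", "cfdna")) {
  class <- match.arg(class)
  feature_set <- match.arg(feature_set)
  clin <- clinical_features(clinical)
  mat <- mom$mom
  clin <- clin[clin$sample_id %in% rownames(mat), , drop = FALSE]
  if (class == "EPE") {
    cf <- epe_cfdna_features(mom, gene_map)
    cf <- cf[clin$sample_id, , drop = FALSE]
    cf_df <- as.data.frame(cf)
  } else {
    ratio <- lpe_cfdna_feature(mom, gene_map)[clin$sample_id]
    cf_df <- data.frame(cfdna_ratio = unname(ratio))
  }
  out <- cbind(clin, cf_df)
  keep_cls <- out$label %in% c("control", class)
  out <- out[keep_cls, , drop = FALSE]
  out$y <- as.integer(out$label == class)
  feats <- switch(feature_set,
                  combined = c(clinical_feature_names(), colnames(cf_df)),
                  clinical = clinical_feature_names(),
                  cfdna = colnames(cf_df))
  out <- out[stats::complete.cases(out[, feats, drop = FALSE]), , drop = FALSE]
  out <- out[, c("sample_id", "dataset", "label", "y", feats), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "schema") <- feats
  attr(out, "schema_hash") <- schema_hash(feats)
  attr(out, "class_context") <- class
  out
}

#' Subset a feature table, preserving its schema attributes
#'
#' Plain `[` subsetting drops the schema attributes the classifiers check;
#' use this to slice feature tables by row.
#'
#' @param features A table from [build_features()].
#' @param i Row index (logical or integer).
#' @return The subset with schema attributes intact.
#' @export
subset_features <- function(features, i) {
  out <- features[i, , drop = FALSE]
  for (a in c("schema", "schema_hash", "class_context")) {
    attr(out, a) <- attr(features, a)
  }
  out
}
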