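# Core data containers and expression transformations.
#
# An ExpressionMatrix is a lightweight S3 list: a non-negative gene x sample
# abundance matrix (FPKM-like, unitless) plus a sample metadata data.frame.
# All downstream stages (module mining, differential expression, network
# inference) consume this one container and select strata via the metadata.

STAGES <- c("L1", "L2", "L3", "L4", "L5")
TISSUES <- c("larva", "nurse_head", "nurse_abdomen")
NURSE_TYPES <- c("stage_specific", "random", "not_applicable")
CASTES <- c("worker", "reproductive", "not_applicable")

METADATA_COLUMNS <- c("sample_id", "tissue", "nurse_type", "stage",
                      "colony", "caste", "queen_present")

#' Construct a validated expression matrix
#'
#' Bundles a gene x sample abundance matrix with typed per-sample metadata.
#' Abundances are FPKM-like: non-negative, unitless, no missing entries.
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns. Column names must match `samples$sample_id` in order.
#' @param samples `data.frame` with columns `sample_id`, `tissue`
#'   (`larva`/`nurse_head`/`nurse_abdomen`), `nurse_type` (`stage_specific`/
#'   `random`/`not_applicable`), `stage` (`L1`..`L5`), `colony`, `caste`
#'   (`worker`/`reproductive`/`not_applicable`) and logical `queen_present`.
#' @return An object of class `ExpressionMatrix` with elements `values` and
#'   `samples`.
#' @details Enforced invariants: all abundances are finite and >= 0; gene
#'   identifiers are unique; larval samples carry `nurse_type =
#'   "not_applicable"`, nurse samples carry `caste = "not_applicable"`; and
#'   each (tissue, nurse_type, stage, colony) combination occurs at most once.
#' @examples
#' v <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1", "s2"), tissue = "larva",
#'                  nurse_type = "not_applicable", stage = c("L1", "L2"),
#'                  colony = "r1", caste = "worker", queen_present = TRUE)
#' expression_matrix(v, md)
#' @export
expression_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite with no missing entries")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance for gene '%s' in sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene identifiers (rownames) must be present and unique")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  missing_cols <- setdiff(METADATA_COLUMNS, names(samples))
  if (length(missing_cols))
    stop("metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  samples <- samples[METADATA_COLUMNS]
  if (is.null(colnames(values)))
    stop("expression matrix must have sample column names")
  if (!identical(colnames(values), as.character(samples$sample_id))) {
    absent <- setdiff(colnames(values), samples$sample_id)
    if (length(absent))
      stop("no metadata for expression column(s): ",
           paste(absent, collapse = ", "))
    samples <- samples[match(colnames(values), samples$sample_id), ,
                       drop = FALSE]
    rownames(samples) <- NULL
  }
  .check_enum(samples$tissue, TISSUES, "tissue")
  .check_enum(samples$nurse_type, NURSE_TYPES, "nurse_type")
  .check_enum(samples$stage, STAGES, "stage")
  .check_enum(samples$caste, CASTES, "caste")
  if (!is.logical(samples$queen_present) || anyNA(samples$queen_present))
    stop("queen_present must be TRUE/FALSE with no missing values")
  larva <- samples$tissue == "larva"
  if (any(samples$nurse_type[larva] != "not_applicable"))
    stop("larval samples must have nurse_type = 'not_applicable'")
  if (any(samples$nurse_type[!larva] == "not_applicable"))
    stop("nurse samples must have nurse_type 'stage_specific' or 'random'")
  if (any(samples$caste[!larva] != "not_applicable"))
    stop("nurse samples must have caste = 'not_applicable'")
  key <- interaction(samples$tissue, samples$nurse_type, samples$stage,
                     samples$colony, samples$caste, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (tissue, nurse_type, stage, colony) combination: ",
         as.character(key[duplicated(key)][1]))
  structure(list(values = values, samples = samples),
            class = "ExpressionMatrix")
}

.check_enum <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad))
    stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                 paste(bad, collapse = ", "), paste(levels, collapse = ", ")))
  invisible(TRUE)
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(tissue = x$samples$tissue, nurse_type = x$samples$nurse_type)
  print(tab)
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Select samples of an expression matrix
#'
#' @param expr `ExpressionMatrix`.
#' @param sample_ids Character vector of sample identifiers to keep (order
#'   preserved).
#' @return `ExpressionMatrix` restricted to the requested samples.
#' @export
subset_samples <- function(expr, sample_ids) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  missing <- setdiff(sample_ids, colnames(expr$values))
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  keep <- match(sample_ids, colnames(expr$values))
  out <- expr
  out$values <- expr$values[, keep, drop = FALSE]
  out$samples <- expr$samples[keep, , drop = FALSE]
  rownames(out$samples) <- NULL
  out
}

# Sample ids matching a stratum; NULL selector means "any value".
.stratum_ids <- function(samples, tissue = NULL, nurse_type = NULL,
                         caste = NULL, stage = NULL, colony = NULL) {
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(tissue)) keep <- keep & samples$tissue %in% tissue
  if (!is.null(nurse_type)) keep <- keep & samples$nurse_type %in% nurse_type
  if (!is.null(caste)) keep <- keep & samples$caste %in% caste
  if (!is.null(stage)) keep <- keep & samples$stage %in% stage
  if (!is.null(colony)) keep <- keep & samples$colony %in% colony
  samples$sample_id[keep]
}

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The expression file is tab-separated with a header row of sample ids and
#' gene identifiers in the first column; the metadata file has the columns
#' `sample_id`, `tissue`, `nurse_type`, `stage`, `colony`, `caste`,
#' `queen_present`.
#'
#' @param path Path to the expression TSV.
#' @param metadata_path Path to the sample metadata TSV.
#' @return A validated [expression_matrix()].
#' @details Fails loudly on malformed input: a non-numeric cell is reported
#'   with its gene/sample coordinates, a negative abundance names the cell,
#'   and an expression column without a metadata row names the column.
#' @export
load_expression <- function(path, metadata_path) {
  for (p in c(path, metadata_path))
    if (!file.exists(p)) stop("file not found: ", p)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("expression file needs gene ids plus >= 1 sample")
  genes <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' for gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], genes[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  }
  rownames(num) <- genes
  md <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                          check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (is.character(md$queen_present))
    md$queen_present <- as.logical(md$queen_present)
  absent <- setdiff(colnames(num), md$sample_id)
  if (length(absent))
    stop("no metadata for expression column(s): ",
         paste(absent, collapse = ", "))
  expression_matrix(num, md)
}

#' Write an expression matrix (and metadata) to TSV files
#'
#' Values are serialised with 17 significant digits so that a
#' [load_expression()] round-trip reproduces them bitwise.
#'
#' @param expr `ExpressionMatrix`.
#' @param path Output path for the expression TSV.
#' @param metadata_path Output path for the metadata TSV (optional).
#' @return Invisibly, `expr`.
#' @export
write_expression <- function(expr, path, metadata_path = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  v <- expr$values
  chr <- array(sprintf("%.17g", v), dim = dim(v))
  out <- data.frame(gene_id = rownames(v), chr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("gene_id", colnames(v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.table(expr$samples, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(expr)
}

#' Per-stage mean abundance for one stratum
#'
#' Averages abundance over all selected samples within each developmental
#' stage L1..L5, the input to log2 fold-change profiles.
#'
#' @param expr `ExpressionMatrix`.
#' @param tissue,nurse_type,caste Stratum selectors; `NULL` selects any value.
#' @param stages Stages required; defaults to all five.
#' @return Numeric matrix, genes x stages.
#' @export
stage_means <- function(expr, tissue = NULL, nurse_type = NULL, caste = NULL,
                        stages = STAGES) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  ids <- .stratum_ids(expr$samples, tissue = tissue, nurse_type = nurse_type,
                      caste = caste)
  sub <- subset_samples(expr, ids)
  empty <- stages[!stages %in% sub$samples$stage]
  if (length(empty))
    stop("no samples for stage(s): ", paste(empty, collapse = ", "))
  out <- vapply(stages, function(s) {
    cols <- sub$samples$sample_id[sub$samples$stage == s]
    rowMeans(sub$values[, cols, drop = FALSE])
  }, numeric(nrow(sub$values)))
  out <- matrix(out, nrow = nrow(sub$values),
                dimnames = list(rownames(expr$values), stages))
  out
}

#' Log2 fold-change stage profiles
#'
#' Converts per-stage mean abundances into the standard five-point profile:
#' `log2((mean_s + pseudocount) / (mean_L1 + pseudocount))`, anchored so that
#' the first entry is exactly 0. The ratio is taken on stage means
#' (ratio-of-means), which is robust to single-replicate zeros; a
#' mean-of-log-ratios alternative can be had by passing per-sample columns.
#'
#' @param stage_means Genes x 5 matrix from [stage_means()].
#' @param pseudocount Positive abundance offset (FPKM scale) keeping
#'   zero-expression stages finite. Default 1.
#' @return Genes x 5 matrix of log2 fold-changes; column 1 is identically 0.
#' @export
log2fc_profiles <- function(stage_means, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      pseudocount <= 0)
    stop("pseudocount must be a single positive number")
  prof <- log2((stage_means + pseudocount) /
                 (stage_means[, 1] + pseudocount))
  prof[, 1] <- 0
  prof
}

#' Inverse hyperbolic sine transform
#'
#' Variance-stabilising transform `x -> ln(x + sqrt(x^2 + 1))` applied to
#' every abundance; monotone, maps 0 to 0, behaves like `log(2x)` for large
#' `x` and is linear near 0.
#'
#' @param expr `ExpressionMatrix` or numeric matrix.
#' @return Object of the same type with transformed values.
#' @export
asinh_transform <- function(expr) {
  if (inherits(expr, "ExpressionMatrix")) {
    expr$values <- asinh(expr$values)
    return(expr)
  }
  asinh(expr)
}

#' Filter genes by minimum per-stage mean abundance
#'
#' Retains genes whose per-stage mean abundance (across all samples, or a
#' stratum if selectors are given) reaches `min_mean` in at least
#' `min_stages` stages.
#'
#' @param expr `ExpressionMatrix`.
#' @param min_mean Minimum per-stage mean abundance (FPKM scale). Default 1.
#' @param min_stages Minimum number of stages meeting `min_mean`. Default 1.
#' @param tissue,nurse_type,caste Optional stratum selectors.
#' @return Character vector of retained gene identifiers.
#' @export
expression_filter <- function(expr, min_mean = 1, min_stages = 1,
                              tissue = NULL, nurse_type = NULL, caste = NULL) {
  stopifnot(min_mean >= 0, min_stages >= 0)
  sm <- stage_means(expr, tissue = tissue, nurse_type = nurse_type,
                    caste = caste)
  keep <- rowSums(sm >= min_mean) >= min_stages
  rownames(sm)[keep]
}

#' Read a per-gene annotation table
#'
#' Tab-separated with columns `gene_id`, `constraint` (selective constraint
#' in \[0,1\], the estimated proportion of nonsynonymous mutations that are
#' strongly deleterious; may be empty), `age_class`
#' (`ancient`/`insect`/`hymenoptera`/`ant`; may be empty), `secreted`
#' (TRUE/FALSE; may be empty) and `gene_sets` (semicolon-delimited set ids).
#'
#' @param path Path to the annotation TSV.
#' @return `data.frame` with one row per gene.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_annotations(ann)
}

#' Validate an annotation table
#'
#' @param ann `data.frame` with columns `gene_id`, `constraint`, `age_class`,
#'   `secreted`, `gene_sets`.
#' @return The validated `data.frame`.
#' @export
validate_annotations <- function(ann) {
  needed <- c("gene_id", "constraint", "age_class", "secreted", "gene_sets")
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols))
    stop("annotation table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene ids in annotations")
  ok <- is.na(ann$constraint) |
    (ann$constraint >= 0 & ann$constraint <= 1)
  if (!all(ok))
    stop("constraint outside [0,1] for gene(s): ",
         paste(ann$gene_id[!ok], collapse = ", "))
  .check_enum(ann$age_class[!is.na(ann$age_class)],
              c("ancient", "insect", "hymenoptera", "ant"), "age_class")
  if (is.character(ann$secreted)) ann$secreted <- as.logical(ann$secreted)
  ann$gene_sets <- as.character(ann$gene_sets)
  ann$gene_sets[is.na(ann$gene_sets)] <- ""
  ann
}
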