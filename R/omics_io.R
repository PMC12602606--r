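#' Read a feature-by-sample matrix from TSV
#'
#' Matrices are plain TSV, UTF-8, no quoting: a header row of sample ids
#' and a first column of feature ids. Validation depends on `kind`:
#' `"beta"` values must be in `[0, 1]` or `NA`; `"counts"` must be
#' non-negative integers with no missing values; `"expr"` must be finite
#' or `NA`.
#'
#' @param path Path to the TSV file.
#' @param kind One of `"beta"`, `"counts"`, `"expr"`.
#' @return Numeric (or integer for counts) matrix with feature rownames
#'   and sample colnames.
#' @export
read_matrix <- function(path, kind = c("beta", "counts", "expr")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           quote = "", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("matrix file needs a feature id column plus >= 1 sample")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))], collapse = ", "))
  }
  x <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(x)) stop("non-numeric values in ", path)
  rownames(x) <- ids
  bad_row <- function(mask) ids[which(rowSums(mask, na.rm = TRUE) > 0)[1]]
  if (kind == "beta") {
    out_of_range <- !is.na(x) & (x < 0 | x > 1)
    if (any(out_of_range)) {
      stop("beta value outside [0, 1] in row ", bad_row(out_of_range))
    }
  } else if (kind == "counts") {
    if (anyNA(x)) stop("missing counts are not allowed (row ", bad_row(is.na(x)), ")")
    bad <- x < 0 | x != floor(x)
    if (any(bad)) {
      stop("counts must be non-negative integers (row ", bad_row(bad), ")")
    }
    storage.mode(x) <- "integer"
  } else {
    if (any(!is.na(x) & !is.finite(x))) {
      stop("non-finite expression value in row ", bad_row(!is.na(x) & !is.finite(x)))
    }
  }
  x
}

#' Write a feature-by-sample matrix as TSV
#'
#' Inverse of [read_matrix()]; numeric values are written with
#' [format()]'s default 15 significant digits so that write-then-read is
#' the identity for doubles. Missing values are written as `NA`.
#'
#' @param x Matrix with rownames and colnames.
#' @param path Output path.
#' @param id_column Name of the feature id column in the header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, id_column = "feature_id") {
  check_feature_matrix(x, "matrix")
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(x))
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Duplicate members within a set are dropped with a
#' warning; lines with fewer than three fields are an error naming the
#' line.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (class `gene_set_collection`);
#'   descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", fields[1], "' deduplicated")
      members <- unique(members)
    }
    if (length(members) == 0) stop("GMT line ", i, ": set '", fields[1], "' is empty")
    sets[[fields[1]]] <- members
    desc[fields[1]] <- fields[2]
  }
  attr(sets, "description") <- desc
  class(sets) <- c("gene_set_collection", "list")
  sets
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named descriptions (defaults to set names).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- stats::setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe manifest TSV
#'
#' BED-like TSV with columns `probe_id`, `chrom`, `pos` (1-based,
#' inclusive), `state`, `gene`. Enforces unique probe ids and the promoter
#' convention: `gene` is non-empty iff `state` is `active_promoter` or
#' `weak_promoter`. Positions are checked against chromosome lengths when
#' a genome is supplied.
#'
#' @param path Path to the manifest TSV.
#' @param genome Optional [toy_genome()] (or data.frame with `chrom`,
#'   `length_bp`) for position validation.
#' @param strict When `FALSE`, promoter/gene convention violations warn
#'   instead of erroring.
#' @return A `probe_manifest` data.frame.
#' @export
read_manifest <- function(path, genome = NULL, strict = TRUE) {
  man <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = c(probe_id = "character", chrom = "character",
                                          pos = "integer", state = "character",
                                          gene = "character"))
  required <- c("probe_id", "chrom", "pos", "state", "gene")
  if (!all(required %in% colnames(man))) {
    stop("manifest must have columns: ", paste(required, collapse = ", "))
  }
  man$gene[!is.na(man$gene) & !nzchar(man$gene)] <- NA_character_
  if (anyDuplicated(man$probe_id)) stop("duplicate probe ids in manifest")
  if (any(man$pos < 1)) stop("positions must be >= 1 (1-based coordinates)")
  is_prom <- man$state %in% c("active_promoter", "weak_promoter")
  viol <- (is_prom & is.na(man$gene)) | (!is_prom & !is.na(man$gene))
  if (any(viol)) {
    msg <- paste0(sum(viol), " probes violate the promoter/gene link convention")
    if (strict) stop(msg) else warning(msg)
  }
  if (!is.null(genome)) {
    len <- genome$length_bp[match(man$chrom, genome$chrom)]
    if (anyNA(len)) stop("manifest chromosomes missing from genome")
    if (any(man$pos > len)) stop("probe position beyond chromosome length")
  }
  class(man) <- c("probe_manifest", "data.frame")
  man
}

#' Write a probe manifest TSV (1-based inclusive coordinates)
#' @param manifest A `probe_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest
  out$gene[is.na(out$gene)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet TSV
#'
#' Enforces unique sample ids, `dfs_event` in {0, 1} and positive tumor
#' sizes where present. All other columns are carried through as-is.
#'
#' @param path Path to the sample sheet TSV.
#' @return data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(sheet)) stop("sample sheet needs a sample_id column")
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample ids in sample sheet")
  if ("dfs_event" %in% colnames(sheet)) {
    ev <- sheet$dfs_event[!is.na(sheet$dfs_event)]
    if (!all(ev %in% c(0, 1))) stop("dfs_event must be 0 or 1")
  }
  if ("tumor_size_cm" %in% colnames(sheet)) {
    sz <- sheet$tumor_size_cm[!is.na(sheet$tumor_size_cm)]
    if (any(sz <= 0)) stop("tumor_size_cm must be > 0 when present")
  }
  sheet
}

#' Write a sample sheet TSV
#' @param sheet data.frame with a `sample_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict methylation, expression and sample sheet to shared samples
#'
#' Keeps the samples present in all three inputs, in the order of the
#' sample sheet, and reports what was dropped — the analysis set of
#' "samples that have both methylome and transcriptome data".
#'
#' @param beta Probe-by-sample beta matrix.
#' @param counts Gene-by-sample count (or expression) matrix.
#' @param sheet Sample sheet with `sample_id`.
#' @return List `beta`, `counts`, `sheet` (identical sample order) and
#'   `dropped`, a named list of sample ids missing from at least one input.
#' @export
align_omics <- function(beta, counts, sheet) {
  check_feature_matrix(beta, "beta")
  check_feature_matrix(counts, "counts")
  shared <- intersect(intersect(colnames(beta), colnames(counts)), sheet$sample_id)
  if (length(shared) < 2) stop("fewer than 2 samples shared across inputs")
  shared <- sheet$sample_id[sheet$sample_id %in% shared]
  dropped <- list(
    beta_only = setdiff(colnames(beta), shared),
    counts_only = setdiff(colnames(counts), shared),
    sheet_only = setdiff(sheet$sample_id, shared)
  )
  list(beta = beta[, shared, drop = FALSE],
       counts = counts[, shared, drop = FALSE],
       sheet = sheet[match(shared, sheet$sample_id), , drop = FALSE],
       dropped = dropped)
}

#' Write a full synthetic cohort to a directory
#'
#' Emits `manifest.tsv`, `beta.tsv`, `counts.tsv`, `samples.tsv` and a
#' `truth.json` ground-truth ledger.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  write_matrix(cohort$beta, file.path(dir, "beta.tsv"), id_column = "probe_id")
  write_matrix(cohort$counts, file.path(dir, "counts.tsv"), id_column = "gene_id")
  write_sample_sheet(cohort$sheet, file.path(dir, "samples.tsv"))
  truth <- cohort$truth
  truth$baseline <- NULL # per-probe baselines are bulky and reproducible from the seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
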