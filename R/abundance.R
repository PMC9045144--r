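#' Read a samples-by-species abundance table
#'
#' Reads a tab-separated table whose first column holds sample identifiers
#' and whose remaining columns hold one species each.  Raw counts are
#' converted to relative abundances by dividing each row by its sum;
#' tables declared `relative` are renormalized as well, so that every row
#' of the returned table sums to exactly 1 (renormalization is a no-op,
#' up to floating point, on a table that already satisfies the
#' constraint).
#'
#' @param path Path to a tab-separated file.  First column: sample id
#'   (any name).  Header row: species names.
#' @param input_kind Either `"counts"` (non-negative counts, rows are
#'   normalized) or `"relative"` (fractions; rows renormalized to guard
#'   against tables whose unclassified fraction was removed upstream).
#' @return A tibble with a `sample_id` character column followed by one
#'   numeric column per species; each row sums to 1.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tsp1\tsp2", "a\t3\t1", "b\t0\t4"), tf)
#' read_abundance(tf, input_kind = "counts")
#' @export
read_abundance <- function(path, input_kind = c("relative", "counts")) {
  input_kind <- match.arg(input_kind)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  if (ncol(raw) < 2) {
    abort("abundance table needs a sample-id column plus at least one species column")
  }
  names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  species <- names(raw)[-1]
  if (anyDuplicated(raw$sample_id)) {
    abort(paste0(
      "duplicate sample ids: ",
      paste(unique(raw$sample_id[duplicated(raw$sample_id)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(species)) {
    abort(paste0(
      "duplicate species columns: ",
      paste(unique(species[duplicated(species)]), collapse = ", ")
    ))
  }
  m <- as.matrix(raw[-1])
  if (!is.numeric(m)) abort("species columns must be numeric")
  if (anyNA(m)) abort("abundance table contains missing values; absent species must be explicit zeros")
  if (any(m < 0)) abort("abundance values must be non-negative")
  normalize_abundance(raw)
}

#' Normalize abundance rows to relative abundances
#'
#' Divides each sample's abundances by their row sum.  Idempotent: applied
#' to an already-relative table it changes nothing beyond floating-point
#' round-off.
#'
#' @param data Data frame: `sample_id` column plus numeric species columns.
#' @return A tibble of the same shape with rows summing to 1.
#' @export
normalize_abundance <- function(data) {
  data <- validate_abundance(data, check_sums = FALSE)
  m <- abundance_matrix(data)
  rs <- rowSums(m)
  if (any(rs == 0)) {
    abort(paste0(
      "sample(s) with zero total abundance: ",
      paste(data$sample_id[rs == 0], collapse = ", ")
    ))
  }
  out <- as_tibble(m / rs)
  dplyr::bind_cols(tibble(sample_id = data$sample_id), out)
}

#' Read a sample metadata table
#'
#' @param path Tab-separated file with mandatory columns `sample_id` and
#'   `group`; `group` must take values in `{athlete, non_athlete}`.  Any
#'   further columns (e.g. `sport`, `study`, `sex`) are kept as character
#'   columns.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(c("sample_id", "group"), names(md))
  if (length(missing) > 0) {
    abort(paste0("metadata is missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(md$group), c("athlete", "non_athlete"))
  if (length(bad) > 0) {
    abort(paste0("unknown group level(s) ", paste(bad, collapse = ", "),
                 "; allowed levels are: athlete, non_athlete"))
  }
  if (anyDuplicated(md$sample_id)) abort("duplicate sample ids in metadata")
  md
}

# Internal: check the samples-by-species tibble contract and return it
# (first column coerced to sample_id).
validate_abundance <- function(data, check_sums = TRUE, tol = 1e-6) {
  if (!is.data.frame(data) || ncol(data) < 2) {
    abort("expected a data frame with a sample-id column plus species columns")
  }
  data <- as_tibble(data)
  names(data)[1] <- "sample_id"
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) abort("duplicate sample ids")
  if (anyDuplicated(names(data)[-1])) abort("duplicate species columns")
  m <- as.matrix(data[-1])
  if (!is.numeric(m)) abort("species columns must be numeric")
  if (anyNA(m)) abort("abundance table contains missing values")
  if (any(m < 0)) abort("abundance values must be non-negative")
  if (check_sums && any(abs(rowSums(m) - 1) > tol)) {
    abort("abundance rows must sum to 1; run normalize_abundance() first")
  }
  data
}

# Internal: samples-by-species numeric matrix with sample_id rownames.
abundance_matrix <- function(data) {
  m <- as.matrix(data[-1])
  rownames(m) <- data$sample_id
  m
}

# Internal: align metadata rows to the table's samples, erroring on gaps.
align_metadata <- function(sample_ids, metadata) {
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    abort("metadata must have sample_id and group columns")
  }
  idx <- match(sample_ids, metadata$sample_id)
  if (anyNA(idx)) {
    abort(paste0("samples without metadata: ",
                 paste(sample_ids[is.na(idx)], collapse = ", ")))
  }
  metadata[idx, , drop = FALSE]
}
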