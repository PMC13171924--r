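#' Read an ASV count table from TSV
#'
#' Reads a tab-separated taxa-by-samples (or samples-by-taxa) table of
#' nonnegative integer read counts. The first column holds identifiers; a
#' leading BIOM-style `"#OTU ID"` header (and any `"# Constructed from ..."`
#' comment line above it) is tolerated. Orientation is normalized so the
#' result is always taxa-by-samples.
#'
#' @param path Path to a TSV file with a header row.
#' @param orientation `"taxa_rows"` (default) if rows are taxa, or
#'   `"samples_rows"` if rows are samples.
#' @return A tibble with a `taxon_id` column followed by one integer column
#'   per sample.
#' @export
read_count_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("count table file not found: ", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  # Drop pure comment lines but keep a "#OTU ID" header row (BIOM TSV export)
  is_comment <- startsWith(lines, "#") & !startsWith(lines, "#OTU ID")
  lines <- lines[!is_comment]
  if (length(lines) < 2L) abort("count table is empty (need a header and at least one row)")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (identical(header[[1L]], "#OTU ID")) header[[1L]] <- "taxon_id"
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  ncol_expected <- length(header)
  bad <- which(lengths(body) != ncol_expected)
  if (length(bad) > 0L) {
    abort(paste0("row ", bad[[1L]] + 1L, " has ", lengths(body)[bad[[1L]]],
                 " fields; expected ", ncol_expected))
  }
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  col_ids <- header[-1L]
  dup_cols <- unique(col_ids[duplicated(col_ids)])
  if (length(dup_cols) > 0L) {
    abort(paste0("duplicate column identifier(s): ", paste(dup_cols, collapse = ", ")))
  }
  dup_rows <- unique(row_ids[duplicated(row_ids)])
  if (length(dup_rows) > 0L) {
    abort(paste0("duplicate row identifier(s): ", paste(dup_rows, collapse = ", ")))
  }
  cells <- matrix("", nrow = length(body), ncol = ncol_expected - 1L)
  for (i in seq_along(body)) cells[i, ] <- body[[i]][-1L]
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad_cell <- which(is.na(num) | num < 0 | num != floor(num), arr.ind = TRUE)
  if (nrow(bad_cell) > 0L) {
    i <- bad_cell[1L, 1L]; j <- bad_cell[1L, 2L]
    abort(paste0("count cell at row '", row_ids[[i]], "', column '", col_ids[[j]],
                 "' is not a nonnegative integer: '", cells[i, j], "'"))
  }
  mat <- matrix(as.integer(num), nrow = length(row_ids),
                dimnames = list(row_ids, col_ids))
  if (orientation == "samples_rows") mat <- t(mat)
  count_matrix_to_tbl(mat)
}

#' Write a count table to TSV
#'
#' Writes the taxa-by-samples table in the same plain TSV dialect
#' [read_count_table()] reads, so integer tables round-trip byte-identically.
#'
#' @param counts A counts tibble (`taxon_id` + sample columns) or a
#'   taxa-by-samples matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  mat <- as_count_matrix(counts)
  lines <- c(
    paste(c("taxon_id", colnames(mat)), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], format(mat[i, ], scientific = FALSE, trim = TRUE)),
            collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `generation`, `compartment`, `cultivar`,
#' `field`, `replicate`. Generation and compartment strings are matched
#' case-insensitively onto the fixed levels; generation becomes an ordered
#' factor `seed < daughter < granddaughter`. A missing `field` (allowed for
#' pre-trial seed tubers) is stored as the explicit level `"(none)"`.
#'
#' @param path Path to a TSV file.
#' @return A tibble of sample metadata.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("metadata file not found: ", path))
  md <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        comment = "#", progress = FALSE)
  needed <- c("sample_id", "generation", "compartment", "cultivar", "field", "replicate")
  missing_cols <- setdiff(needed, names(md))
  if (length(missing_cols) > 0L) {
    abort(paste0("metadata is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  validate_metadata(as_tibble(md[needed]))
}

#' Validate and canonicalize a metadata tibble
#'
#' @param metadata A data frame with the columns listed in [read_metadata()].
#' @return A validated tibble with canonical factor levels.
#' @export
validate_metadata <- function(metadata) {
  md <- as_tibble(metadata)
  dup <- unique(md$sample_id[duplicated(md$sample_id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate sample_id in metadata: ", paste(dup, collapse = ", ")))
  }
  match_level <- function(x, levels, what) {
    idx <- match(tolower(as.character(x)), tolower(levels))
    bad <- unique(as.character(x)[is.na(idx) & !is.na(x)])
    if (length(bad) > 0L) {
      abort(paste0("unknown ", what, " level(s): ", paste(bad, collapse = ", "),
                   "; accepted: ", paste(levels, collapse = ", ")))
    }
    levels[idx]
  }
  gen <- match_level(md$generation, tt_generation_levels, "generation")
  if (anyNA(gen)) abort("generation may not be missing")
  comp <- match_level(md$compartment, tt_compartment_levels, "compartment")
  if (anyNA(comp)) abort("compartment may not be missing")
  field <- as.character(md$field)
  field[is.na(field) | field == ""] <- tt_no_field
  rep_num <- suppressWarnings(as.integer(md$replicate))
  if (anyNA(rep_num) || any(rep_num < 1L)) {
    abort("replicate must be a positive integer for every sample")
  }
  soil_early <- comp == "tare_soil" & gen != "granddaughter"
  if (any(soil_early)) {
    warn(paste0("tare_soil samples at generation other than granddaughter: ",
                paste(md$sample_id[soil_early], collapse = ", ")))
  }
  tibble(
    sample_id = as.character(md$sample_id),
    generation = factor(gen, levels = tt_generation_levels, ordered = TRUE),
    compartment = factor(comp, levels = tt_compartment_levels),
    cultivar = as.character(md$cultivar),
    field = field,
    replicate = rep_num
  )
}

#' Write sample metadata to TSV
#'
#' @param metadata A metadata tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata
  out$generation <- as.character(out$generation)
  out$compartment <- as.character(out$compartment)
  out$field[out$field == tt_no_field] <- ""
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

count_matrix_to_tbl <- function(mat) {
  out <- as_tibble(as.data.frame(mat, check.names = FALSE, stringsAsFactors = FALSE))
  tibble(taxon_id = rownames(mat)) |> dplyr::bind_cols(out)
}

#' Convert a counts tibble to a taxa-by-samples matrix
#'
#' @param counts A counts tibble with a `taxon_id` first column, or an
#'   already-formed numeric matrix with dimnames (returned unchanged after
#'   validation).
#' @return A numeric taxa-by-samples matrix with taxon row names.
#' @export
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    mat <- counts
    if (is.null(rownames(mat)) || is.null(colnames(mat))) {
      abort("count matrix must have taxon row names and sample column names")
    }
  } else {
    counts <- as_tibble(counts)
    id_col <- if ("taxon_id" %in% names(counts)) "taxon_id" else names(counts)[[1L]]
    mat <- as.matrix(counts[setdiff(names(counts), id_col)])
    rownames(mat) <- as.character(counts[[id_col]])
  }
  if (nrow(mat) < 1L || ncol(mat) < 1L) abort("count table needs at least 1 taxon and 1 sample")
  if (anyDuplicated(rownames(mat))) abort("duplicate taxon identifiers in count table")
  if (anyDuplicated(colnames(mat))) abort("duplicate sample identifiers in count table")
  if (anyNA(mat) || any(mat < 0)) abort("counts must be nonnegative and non-missing")
  mat
}

#' Assemble a validated dataset from counts and metadata
#'
#' Checks that the count table and metadata describe exactly the same set of
#' samples and reorders the count columns to the metadata row order.
#'
#' @param counts Counts tibble or taxa-by-samples matrix.
#' @param metadata Metadata tibble (see [read_metadata()]).
#' @return A `tt_dataset`: a list with `counts` (integer matrix, taxa x
#'   samples) and `metadata` (tibble), aligned by sample.
#' @export
validate_dataset <- function(counts, metadata) {
  mat <- as_count_matrix(counts)
  md <- validate_metadata(metadata)
  only_counts <- setdiff(colnames(mat), md$sample_id)
  only_md <- setdiff(md$sample_id, colnames(mat))
  if (length(only_counts) > 0L || length(only_md) > 0L) {
    abort(paste0(
      "sample sets differ between counts and metadata; ",
      "only in counts: {", paste(only_counts, collapse = ", "), "}; ",
      "only in metadata: {", paste(only_md, collapse = ", "), "}"
    ))
  }
  mat <- mat[, md$sample_id, drop = FALSE]
  structure(list(counts = mat, metadata = md), class = "tt_dataset")
}

#' @export
print.tt_dataset <- function(x, ...) {
  cat("<tt_dataset> ", nrow(x$counts), " taxa x ", ncol(x$counts), " samples\n", sep = "")
  cat("  generations: ", paste(levels(droplevels(x$metadata$generation)), collapse = " < "), "\n", sep = "")
  cat("  compartments: ", paste(sort(unique(as.character(x$metadata$compartment))), collapse = ", "), "\n", sep = "")
  cat("  cultivars: ", paste(sort(unique(x$metadata$cultivar)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Partition samples into groups by metadata factors
#'
#' @param ds A `tt_dataset`.
#' @param by Character vector of factor names, a subset of
#'   `c("generation", "compartment", "cultivar", "field")`. An empty vector
#'   yields a single group holding every sample.
#' @return A tibble with one row per group: the grouping columns, `n_samples`,
#'   and a `sample_ids` list-column. Groups are disjoint and exhaustive.
#' @export
group_samples <- function(ds, by = c("generation", "compartment", "cultivar")) {
  stopifnot(inherits(ds, "tt_dataset"))
  allowed <- c("generation", "compartment", "cultivar", "field")
  bad <- setdiff(by, allowed)
  if (length(bad) > 0L) {
    abort(paste0("unknown grouping factor(s): ", paste(bad, collapse = ", "),
                 "; allowed: ", paste(allowed, collapse = ", ")))
  }
  md <- ds$metadata
  if (length(by) == 0L) {
    return(tibble(n_samples = nrow(md), sample_ids = list(md$sample_id)))
  }
  md |>
    group_by(across(all_of(by))) |>
    summarise(n_samples = n(), sample_ids = list(.data$sample_id), .groups = "drop")
}

#' Write a result tibble to TSV with a provenance header
#'
#' All result writers share one format: a single `# tubertrace <version>
#' <stage>` comment line followed by a plain TSV body.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @param stage Short stage name recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path, stage = "result") {
  header <- paste0("# tubertrace ", as.character(packageVersion("tubertrace")), " ", stage)
  writeLines(header, path, useBytes = TRUE)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
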