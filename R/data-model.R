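## Domain containers and file readers. Every downstream module consumes
## these validated types only; all joins go through the sample design
## (opaque sample ids), never through positional order.

#' Construct a sample design table
#'
#' Describes the experimental layout: which sample belongs to which
#' treatment, sampling day and replicate. The emulated study uses three
#' treatments (CK, T1, T5 at 0, 180 and 900 g a.i. ha\eqn{^{-1}}), three
#' replicates and seven sampling days (0, 1, 5, 10, 20, 30, 60), i.e. 63
#' samples, but any layout is accepted.
#'
#' @param sample_id character, unique sample identifiers.
#' @param treatment character treatment labels (e.g. "CK", "T1", "T5").
#' @param day integer days post-application.
#' @param replicate positive integer replicate index.
#' @param dose numeric dose in g a.i. per hectare; defaults to \code{NA}.
#' @return A \code{sample_design} data frame.
#' @export
sample_design <- function(sample_id, treatment, day, replicate, dose = NA_real_) {
  d <- data.frame(
    sample_id = as.character(sample_id),
    treatment = as.character(treatment),
    dose = as.numeric(dose),
    day = as.integer(day),
    replicate = as.integer(replicate),
    stringsAsFactors = FALSE
  )
  validate_sample_design(d)
}

validate_sample_design <- function(d) {
  assert_that(!anyDuplicated(d$sample_id), "duplicate sample_id in design",
              class = "schema_error")
  key <- paste(d$treatment, d$day, d$replicate, sep = "\r")
  assert_that(!anyDuplicated(key),
              "(treatment, day, replicate) combinations must be unique",
              class = "schema_error")
  assert_that(all(is.na(d$dose) | d$dose >= 0), "dose must be >= 0")
  assert_that(all(d$replicate >= 1L), "replicate must be a positive integer")
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Read sample metadata from CSV
#'
#' Expects a header with columns \code{sample_id}, \code{treatment},
#' \code{day}, \code{replicate} and optionally \code{dose}.
#'
#' @param path CSV file path.
#' @return A \code{sample_design} data frame.
#' @export
read_sample_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "treatment", "day", "replicate")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop2("metadata is missing column(s): ", paste(missing, collapse = ", "),
          class = "format_error")
  sample_design(d$sample_id, d$treatment, d$day, d$replicate,
                dose = if ("dose" %in% names(d)) d$dose else NA_real_)
}

#' Construct a plate reading set
#'
#' Long-form Biolog EcoPlate signal records: one row per (sample, well,
#' time point). Signals are OmniLog units, nonnegative. Blank wells carry
#' the substrate name \code{"Water"}. Each plate must contain exactly the
#' 31 catalog substrates (non-blank) and an identical time grid across
#' wells.
#'
#' @param records data frame with columns \code{sample_id}, \code{well_id},
#'   \code{substrate}, \code{time_h}, \code{signal}.
#' @return A \code{plate_readings} object (validated data frame).
#' @seealso [read_plate_readings()], [eco_substrates()]
#' @export
plate_readings <- function(records) {
  need <- c("sample_id", "well_id", "substrate", "time_h", "signal")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop2("plate records missing column(s): ", paste(missing, collapse = ", "),
          class = "format_error")
  if (nrow(records) == 0L)
    stop2("plate file contains no records", class = "format_error")
  assert_that(all(records$signal >= 0), "negative signal values present")
  assert_that(all(records$time_h >= 0), "negative incubation times present")

  blank <- is_blank_substrate(records$substrate)
  canon <- match_substrate(records$substrate)
  unmatched <- unique(records$substrate[!blank & is.na(canon)])
  if (length(unmatched))
    stop2("substrate name(s) not in the 31-substrate EcoPlate catalog: ",
          paste(utils::head(unmatched, 5L), collapse = ", "),
          class = "schema_error")
  records$substrate[!blank] <- canon[!blank]
  records$substrate[blank] <- "Water"

  ## per-plate checks: 31 distinct non-blank substrates, shared time grid
  for (s in unique(records$sample_id)) {
    r <- records[records$sample_id == s, ]
    subs <- unique(r$substrate[r$substrate != "Water"])
    if (length(subs) != 31L)
      stop2("sample ", s, " has ", length(subs),
            " non-blank substrates; an EcoPlate has 31", class = "schema_error")
    grids <- tapply(r$time_h, r$well_id, function(t) paste(sort(unique(t)), collapse = ","))
    if (length(unique(grids)) != 1L)
      stop2("sample ", s, " has an inconsistent time grid across wells",
            class = "schema_error")
  }
  structure(records, class = c("plate_readings", "data.frame"))
}

#' Read EcoPlate signals from long-form CSV
#'
#' @param path CSV with header
#'   \code{sample_id,well_id,substrate,time_h,signal}.
#' @return A validated \code{plate_readings} object; blank wells are the
#'   rows whose substrate is \code{"Water"}.
#' @export
read_plate_readings <- function(path) {
  d <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop2("cannot parse plate CSV: ",
                                          conditionMessage(e),
                                          class = "format_error"))
  plate_readings(d)
}

#' @export
print.plate_readings <- function(x, ...) {
  cat("<plate_readings> ", length(unique(x$sample_id)), " plates, ",
      length(unique(x$time_h)), " time points, ",
      nrow(x), " records\n", sep = "")
  invisible(x)
}

#' Construct a feature-abundance table
#'
#' Features x samples nonnegative matrix with a declared feature rank
#' (genus, phylum, gene, cazy_family or kegg_category) and an optional
#' feature-to-parent map (e.g. genus to phylum).
#'
#' @param matrix numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param rank one of \code{"genus"}, \code{"phylum"}, \code{"gene"},
#'   \code{"cazy_family"}, \code{"kegg_category"}.
#' @param is_relative logical; if \code{TRUE} each column must sum to 1.
#' @param feature_parent optional named character vector mapping feature id
#'   to a parent feature id.
#' @return An \code{abundance_table} object.
#' @export
abundance_table <- function(matrix, rank, is_relative = FALSE,
                            feature_parent = NULL) {
  ranks <- c("genus", "phylum", "gene", "cazy_family", "kegg_category")
  rank <- match.arg(rank, ranks)
  m <- as.matrix(matrix)
  assert_that(!is.null(rownames(m)), "abundance matrix needs feature rownames",
              class = "schema_error")
  assert_that(!is.null(colnames(m)), "abundance matrix needs sample colnames",
              class = "schema_error")
  if (anyDuplicated(rownames(m)))
    stop2("duplicate feature ids in abundance table", class = "schema_error")
  if (any(m < 0)) stop2("negative entries in abundance table")
  if (is_relative) {
    cs <- colSums(m)
    assert_that(all(abs(cs - 1) <= 1e-9),
                "declared relative table has columns not summing to 1")
  }
  structure(list(matrix = m, rank = rank, is_relative = is_relative,
                 feature_parent = feature_parent),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> rank=", x$rank, ": ", nrow(x$matrix), " features x ",
      ncol(x$matrix), " samples",
      if (x$is_relative) " (relative)" else " (counts/raw)", "\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$matrix)

#' Read a feature-abundance TSV
#'
#' First column holds feature ids, remaining columns are samples. Counts
#' are preserved exactly.
#'
#' @param path TSV file.
#' @param rank declared feature rank (see [abundance_table()]).
#' @return An \code{abundance_table}.
#' @export
read_abundance_table <- function(path, rank) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(d) < 2L)
    stop2("abundance TSV needs a feature-id column plus >= 1 sample column",
          class = "format_error")
  ids <- as.character(d[[1L]])
  if (anyDuplicated(ids))
    stop2("duplicate feature id in abundance table: ",
          ids[duplicated(ids)][1L], class = "schema_error")
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  abundance_table(m, rank = rank)
}

#' Write a feature-abundance TSV
#'
#' Inverse of [read_abundance_table()]; values round-trip to at least
#' 1e-6 (full precision is written).
#'
#' @param table an \code{abundance_table}.
#' @param path output TSV path.
#' @return invisibly, \code{path}.
#' @export
write_abundance_table <- function(table, path) {
  d <- data.frame(feature_id = rownames(table$matrix),
                  table$matrix, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
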