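#' Read and write pipeline tables
#'
#' Tab-delimited text readers/writers for the package's tabular interfaces:
#' cohort tables (one row per subject), morphometric tables (long format,
#' \code{subject_id}, \code{region_id}, then one column per feature —
#' mirroring FreeSurfer-style regional exports so real data can be swapped
#' in), and metric tables from [compute_metrics()]. All writers are
#' deterministic: identical inputs give byte-identical files.
#'
#' @param x Object to write.
#' @param path File path.
#' @name msn_io
NULL

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname msn_io
#' @export
write_cohort <- function(x, path) write_tsv(x, path)

#' @rdname msn_io
#' @export
read_cohort <- function(path) {
  coh <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "diagnosis", "disinhibition_present",
            "disinhibition_severity", "age", "sex", "education", "cdr_sb",
            "tiv", "days_mri_npiq", "scanner")
  miss <- setdiff(need, names(coh))
  if (length(miss) > 0)
    stop("cohort file missing column(s): ", paste(miss, collapse = ", "))
  coh$diagnosis <- factor(coh$diagnosis, levels = c("DAT", "bvFTD"))
  coh$sex <- factor(coh$sex, levels = c("M", "F"))
  coh$scanner <- factor(coh$scanner, levels = c("Siemens", "GE", "Philips"))
  coh$disinhibition_present <- as.logical(coh$disinhibition_present)
  if (any(coh$disinhibition_present != (coh$disinhibition_severity >= 1)))
    stop("cohort file violates presence == (severity >= 1)")
  coh
}

#' @rdname msn_io
#' @export
write_morphometry <- function(x, path) {
  stopifnot(inherits(x, "msn_morphometry") || is.list(x))
  long <- do.call(rbind, lapply(names(x), function(sid) {
    m <- x[[sid]]
    data.frame(subject_id = sid, region_id = rownames(m),
               as.data.frame(m, row.names = FALSE),
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  write_tsv(long, path)
}

#' @rdname msn_io
#' @export
read_morphometry <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("subject_id", "region_id") %in% names(long)))
    stop("morphometry file needs subject_id and region_id columns")
  feats <- setdiff(names(long), c("subject_id", "region_id"))
  sids <- unique(long$subject_id)
  out <- lapply(sids, function(sid) {
    sub <- long[long$subject_id == sid, , drop = FALSE]
    m <- as.matrix(sub[feats])
    rownames(m) <- sub$region_id
    m
  })
  names(out) <- sids
  structure(out, region_id = out[[1]] |> rownames(), features = feats,
            class = "msn_morphometry")
}

#' @rdname msn_io
#' @export
write_metrics <- function(x, path) write_tsv(x, path)

#' @rdname msn_io
#' @export
read_metrics <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Write a similarity matrix as delimited text
#'
#' Square matrix with a region-id header row and column, readable back with
#' [read_msn_matrix()].
#'
#' @param W Similarity matrix with region-id dimnames.
#' @param path File path.
#' @export
write_msn_matrix <- function(W, path) {
  df <- data.frame(region_id = rownames(W), W, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @rdname write_msn_matrix
#' @export
read_msn_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df$region_id
  W
}
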