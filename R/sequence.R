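#' Create a sequence record
#'
#' A lightweight container for a protein (sub)sequence: an identifier, the
#' residues as one-letter codes, and optionally the 1-based inclusive region
#' within a parent sequence the residues were cut from.
#'
#' @param id Character identifier.
#' @param seq Character scalar (one-letter codes) or character vector of
#'   single letters.
#' @param region Optional integer vector `c(start, end)`, 1-based inclusive
#'   coordinates within the parent sequence.
#' @param allow_x Allow the ambiguity code `X` (default `FALSE`).
#' @return An object of class `idr_seq` with elements `id`, `residues`
#'   and `region`.
#' @examples
#' s <- idr_seq("demo", "ADPWGGDPWK")
#' length(s$residues)
#' @export
idr_seq <- function(id, seq, region = NULL, allow_x = FALSE) {
  if (length(seq) == 1 && nchar(seq[1]) != 1) {
    residues <- strsplit(toupper(seq), "")[[1]]
  } else {
    residues <- toupper(as.character(seq))
  }
  validate_residues(residues, allow_x = allow_x)
  if (!is.null(region)) {
    region <- as.integer(region)
    if (length(region) != 2 || region[2] < region[1]) {
      stop("region must be c(start, end) with end >= start", call. = FALSE)
    }
    if (region[2] - region[1] + 1L != length(residues)) {
      stop("region width does not match the number of residues", call. = FALSE)
    }
  }
  structure(list(id = as.character(id), residues = residues, region = region),
            class = "idr_seq")
}

#' @export
print.idr_seq <- function(x, ...) {
  reg <- if (is.null(x$region)) "" else
    sprintf(" [region %d-%d]", x$region[1], x$region[2])
  cat(sprintf("<idr_seq> %s%s, %d residues\n", x$id, reg, length(x$residues)))
  invisible(x)
}

#' @export
length.idr_seq <- function(x) length(x$residues)

#' @noRd
as_idr_seq <- function(x) {
  if (inherits(x, "idr_seq")) return(x)
  if (is.character(x)) return(idr_seq("seq", x))
  stop("cannot interpret input as a sequence record", call. = FALSE)
}

#' Read a (sub)region of a FASTA record
#'
#' Reads a multi-record FASTA file (line wrapping is irrelevant) and returns
#' one record, optionally restricted to a 1-based inclusive region.
#'
#' @param path Path to a FASTA file.
#' @param id Record to extract; `NULL` (default) takes the first record.
#'   Matched as a prefix of the FASTA header.
#' @param region Optional `c(start, end)` region to cut out.
#' @return An [idr_seq] object.
#' @export
read_fasta_region <- function(path, id = NULL, region = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no records in FASTA file: ", path, call. = FALSE)
  idx <- 1L
  if (!is.null(id)) {
    idx <- which(startsWith(names(set), id))
    if (length(idx) == 0) stop("no FASTA record matching id: ", id, call. = FALSE)
    idx <- idx[1]
  }
  full <- as.character(set[[idx]])
  name <- sub("\\s.*$", "", names(set)[idx])
  if (!is.null(region)) {
    region <- as.integer(region)
    if (region[1] < 1 || region[2] > nchar(full)) {
      stop("region out of bounds for sequence of length ", nchar(full),
           call. = FALSE)
    }
    full <- substr(full, region[1], region[2])
  }
  idr_seq(name, full, region = region)
}
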