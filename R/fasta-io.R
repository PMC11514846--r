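# Uppercase IUPAC nucleotide alphabet accepted after normalization.
IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N")
.invalid_iupac_regex <- "[^ACGTRYSWKMBDHVN]"

#' Construct a genome record
#'
#' A genome record holds one normalized sequence together with its FASTA
#' header, split into `id` (first whitespace-delimited token) and
#' `description` (the remainder, possibly empty).
#'
#' @param id Record identifier; non-empty string without whitespace.
#' @param sequence Normalized sequence: uppercase IUPAC letters only.
#' @param description Free-text remainder of the header.
#' @param u_converted Number of U characters mapped to T during
#'   normalization (RNA input).
#' @param gaps_removed Number of gap characters (`-`, `.`) stripped during
#'   normalization.
#' @return An object of class `genome_record`.
#' @seealso [read_fasta()], [normalize_sequence()]
#' @export
genome_record <- function(id, sequence, description = "",
                          u_converted = 0L, gaps_removed = 0L) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id))
    stop("record id must be a non-empty string without whitespace")
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop(sprintf("record '%s': sequence must be a non-empty string", id))
  bad <- regexpr(.invalid_iupac_regex, sequence)
  if (bad > 0L)
    stop(sprintf("record '%s': invalid character '%s' at position %d",
                 id, substr(sequence, bad, bad), bad))
  structure(
    list(id = id, description = description, sequence = sequence,
         u_converted = as.integer(u_converted),
         gaps_removed = as.integer(gaps_removed)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%d bp)%s\n", x$id, nchar(x$sequence),
              if (nzchar(x$description)) paste0(" - ", x$description) else ""))
  invisible(x)
}

#' Normalize a raw nucleotide sequence
#'
#' Uppercases, maps U to T (so RNA genomes are analyzable), strips gap
#' characters `-` and `.` (alignment columns pasted as FASTA), and
#' validates that everything left is an IUPAC nucleotide letter.
#' Normalizing an already-normalized sequence is a no-op.
#'
#' @param sequence Raw sequence string.
#' @return A list with elements `sequence` (normalized string),
#'   `u_converted` and `gaps_removed` (integer tallies).
#' @export
normalize_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single string")
  s <- toupper(sequence)
  n0 <- nchar(s)
  s <- gsub("[-.]", "", s)
  gaps_removed <- n0 - nchar(s)
  n1 <- nchar(s)
  u_converted <- n1 - nchar(gsub("U", "", s, fixed = TRUE))
  if (u_converted > 0L) s <- chartr("U", "T", s)
  bad <- regexpr(.invalid_iupac_regex, s)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d (after normalization)",
                 substr(s, bad, bad), bad))
  list(sequence = s, u_converted = as.integer(u_converted),
       gaps_removed = as.integer(gaps_removed))
}

#' Read a (multi-record) FASTA file
#'
#' Records are returned in file order; wrapped sequence lines are
#' concatenated and each sequence is passed through
#' [normalize_sequence()]. Soft-masked (lowercase) bases are uppercased
#' and counted like any other base: masking marks repeats, not
#' composition. A single warning reports the total number of gap
#' characters stripped, if any.
#'
#' @param path Path to a FASTA file.
#' @return A list of [genome_record()] objects.
#' @export
read_fasta <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("path must be a single file path")
  if (!file.exists(path))
    stop(sprintf("FASTA file not found: '%s'", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("'%s' is not readable FASTA: %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (length(set) == 0L)
    stop(sprintf("'%s' contains no FASTA records", path))
  headers <- names(set)
  seqs <- unname(as.character(set))
  records <- vector("list", length(set))
  for (i in seq_along(set)) {
    header <- if (is.null(headers) || is.na(headers[i])) "" else headers[i]
    id <- sub("\\s.*$", "", header)
    if (!nzchar(id))
      stop(sprintf("record #%d in '%s' has an empty header", i, path))
    description <- if (grepl("\\s", header))
      sub("^\\S+\\s+", "", header) else ""
    if (!nzchar(seqs[i]))
      stop(sprintf("record '%s' in '%s' has an empty sequence", id, path))
    norm <- tryCatch(
      normalize_sequence(seqs[i]),
      error = function(e) stop(sprintf("record '%s' in '%s': %s", id, path,
                                       conditionMessage(e)), call. = FALSE)
    )
    if (!nzchar(norm$sequence))
      stop(sprintf("record '%s' in '%s' is empty after normalization",
                   id, path))
    records[[i]] <- genome_record(id, norm$sequence, description,
                                  u_converted = norm$u_converted,
                                  gaps_removed = norm$gaps_removed)
  }
  total_gaps <- sum(vapply(records, `[[`, integer(1), "gaps_removed"))
  if (total_gaps > 0L)
    warning(sprintf("removed %d gap character(s) ('-'/'.') while reading '%s'",
                    total_gaps, path))
  total_u <- sum(vapply(records, `[[`, integer(1), "u_converted"))
  if (total_u > 0L)
    message(sprintf("mapped %d U character(s) to T while reading '%s'",
                    total_u, path))
  records
}

#' Write genome records to FASTA
#'
#' Writes records so that [read_fasta()] reproduces their ids and
#' sequences exactly (round-trip identity).
#'
#' @param records A list of [genome_record()] objects (or a single one).
#' @param path Output file path.
#' @param line_width Sequence line wrap width (positive integer).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, line_width = 70L) {
  if (inherits(records, "genome_record")) records <- list(records)
  if (!is.list(records) || length(records) == 0L)
    stop("records must be a non-empty list of genome_record objects")
  if (!all(vapply(records, inherits, logical(1), "genome_record")))
    stop("records must all be genome_record objects")
  line_width <- as.integer(line_width)
  if (is.na(line_width) || line_width < 1L)
    stop("line_width must be a positive integer")
  ids <- vapply(records, `[[`, character(1), "id")
  descs <- vapply(records, `[[`, character(1), "description")
  seqs <- vapply(records, `[[`, character(1), "sequence")
  headers <- ifelse(nzchar(descs), paste(ids, descs), ids)
  set <- Biostrings::BStringSet(seqs)
  names(set) <- headers
  tryCatch(
    Biostrings::writeXStringSet(set, filepath = path, width = line_width),
    error = function(e) stop(sprintf("cannot write FASTA to '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  invisible(path)
}
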