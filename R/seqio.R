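#' Build a set of validated protein records
#'
#' Constructs the package's basic sequence container: a data frame with one
#' row per protein, columns `id`, `sequence` and `length`. Sequences are
#' uppercased and checked against the 20-letter alphabet ([AA_ALPHABET]).
#'
#' Ambiguous or non-standard residue codes (B, J, O, U, X, Z, ...) are
#' handled according to `strict`: in strict mode any such character is an
#' error naming the record and the offending character; in lenient mode the
#' character is dropped with a warning and the record length shrinks
#' accordingly. Every downstream feature formula is defined only over the
#' 20 canonical residues, so there is no third option.
#'
#' @param id Character vector of record identifiers.
#' @param sequence Character vector of amino-acid sequences (same length
#'   as `id`).
#' @param strict Logical; reject (`TRUE`, default) or drop (`FALSE`)
#'   non-canonical residues.
#' @return A `protein_records` data frame with columns `id`, `sequence`,
#'   `length`.
#' @export
protein_records <- function(id, sequence, strict = TRUE) {
  stopifnot(length(id) == length(sequence))
  id <- as.character(id)
  sequence <- toupper(gsub("[[:space:]]+", "", as.character(sequence)))
  for (i in seq_along(sequence)) {
    chars <- strsplit(sequence[i], "", fixed = TRUE)[[1]]
    bad <- !(chars %in% AA_ALPHABET)
    if (any(bad)) {
      if (strict) {
        stop(
          "record '", id[i], "' contains non-standard residue(s): ",
          paste(unique(chars[bad]), collapse = ", "),
          call. = FALSE
        )
      }
      warning(
        "record '", id[i], "': dropped ", sum(bad),
        " non-standard residue(s) (",
        paste(unique(chars[bad]), collapse = ", "), ")",
        call. = FALSE
      )
      sequence[i] <- paste(chars[!bad], collapse = "")
    }
  }
  if (any(nchar(sequence) == 0L)) {
    stop(
      "empty sequence for record(s): ",
      paste(id[nchar(sequence) == 0L], collapse = ", "),
      call. = FALSE
    )
  }
  out <- data.frame(
    id = id, sequence = sequence, length = nchar(sequence),
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-record) FASTA file. The header token before the first
#' whitespace becomes the record id; sequences are uppercased and internal
#' whitespace is removed. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @inheritParams protein_records
#' @return A `protein_records` data frame.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: '", path, "'", call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("no FASTA records in '", path, "'", call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  protein_records(ids, as.character(set), strict = strict)
}

#' Write protein records to a FASTA file
#'
#' @param records A `protein_records` data frame (or anything with `id`
#'   and `sequence` columns).
#' @param path Output file path.
#' @param width Line width for sequence wrapping (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  set <- Biostrings::BStringSet(stats::setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# Shared reader for the package's 2-column TSV side tables
# (id <TAB> value). '#' comment lines and blank lines are ignored; an
# optional header row is recognised by its first field.
read_two_column_tsv <- function(path, value_name,
                                header_words = c("id", "record_id")) {
  if (!file.exists(path)) {
    stop("file not found: '", path, "'", call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    stop("no data rows in '", path, "'", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("'", path, "' is not a 2-column tab-separated table", call. = FALSE)
  }
  if (tolower(fields[[1]][1]) %in% header_words) {
    fields <- fields[-1L]
  }
  out <- data.frame(
    id = vapply(fields, `[`, "", 1L),
    value = vapply(fields, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  names(out)[2L] <- value_name
  out
}

#' Read a sequence label table
#'
#' Reads a 2-column TSV (`id<TAB>label`); `#` comments are ignored and a
#' header row is optional.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `id` and `label`.
#' @export
read_labels <- function(path) {
  read_two_column_tsv(path, "label")
}

#' Read a family-annotation table
#'
#' Reads a 2-column TSV (`record_id<TAB>family_id`) mapping sequence ids to
#' protein-family ids, as used by [select_longest_per_family()]. `#`
#' comments are ignored and a header row is optional. Record ids must be
#' unique.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `record_id` and `family_id`.
#' @export
read_family_annotations <- function(path) {
  out <- read_two_column_tsv(path, "family_id")
  names(out)[1L] <- "record_id"
  if (anyDuplicated(out$record_id)) {
    stop(
      "duplicated record_id in '", path, "': ",
      paste(unique(out$record_id[duplicated(out$record_id)]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' Select the longest sequence of each protein family
#'
#' Dataset-curation rule for building a non-redundant negative set: keep
#' exactly one representative per family — the longest member — and skip
#' families listed in `excluded_families` (e.g. families that contain
#' positive instances, which must not contribute negatives). Length ties
#' within a family are broken by the lexicographically smallest id, so the
#' selection is deterministic regardless of input order.
#'
#' @param records A `protein_records` data frame.
#' @param annotations Data frame with columns `record_id`, `family_id`
#'   (see [read_family_annotations()]); every record id must be annotated.
#' @param excluded_families Character vector of family ids to drop.
#' @return A `protein_records` data frame with one row per non-excluded
#'   family, ordered by family id.
#' @export
select_longest_per_family <- function(records, annotations,
                                      excluded_families = character()) {
  fam <- annotations$family_id[match(records$id, annotations$record_id)]
  if (anyNA(fam)) {
    stop(
      "record(s) without family annotation: ",
      paste(records$id[is.na(fam)], collapse = ", "),
      call. = FALSE
    )
  }
  keep <- !(fam %in% excluded_families)
  records <- records[keep, , drop = FALSE]
  fam <- fam[keep]
  # longest per family; ties -> lexicographically smallest id
  ord <- order(fam, -nchar(records$sequence), records$id)
  first <- !duplicated(fam[ord])
  out <- records[ord[first], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protein_records", "data.frame")
  out
}

# Coerce the various sequence inputs (protein_records, named or unnamed
# character vector) to a named character vector of validated sequences.
as_sequences <- function(records) {
  if (is.data.frame(records)) {
    stats::setNames(records$sequence, records$id)
  } else if (is.character(records)) {
    seqs <- toupper(records)
    if (is.null(names(seqs))) {
      names(seqs) <- paste0("seq", seq_along(seqs))
    }
    seqs
  } else {
    stop("cannot interpret 'records' as protein sequences", call. = FALSE)
  }
}
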