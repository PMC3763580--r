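#' @name ctd-features
#' @title CTD feature families for protein sequences
#'
#' @description
#' Four feature families describe a protein sequence `S = R1...RL` over the
#' 20-letter alphabet and a three-group partition of that alphabet per
#' physicochemical property:
#'
#' * [aa_composition()] — 20 features: the frequency `n_i / L` of each
#'   residue.
#' * [ctd_content()] — 24 features (8 properties x 3 groups): the fraction
#'   of residues falling in each group. Per property the three values sum
#'   to 1 because the groups partition the alphabet.
#' * [ctd_transition()] — 24 features (8 properties x 3 unordered group
#'   pairs): bivalent frequency, i.e. the number of adjacent residue pairs
#'   whose members fall in the two groups of the pair (in either order),
#'   divided by `L`.
#' * [ctd_distribution()] — 120 features (8 properties x 3 groups x 5
#'   chain fractions): for each group, the 1-based position of the first,
#'   25%, 50%, 75% and 100% occurrence of a group member, divided by `L`.
#'   The k-th quantile occurrence uses `k = ceiling(q * n_g)` over the
#'   `n_g` occurrences, so the 100% feature is the last occurrence
#'   exactly. A group with no members in the sequence contributes five
#'   zeros.
#'
#' All features lie in `[0, 1]`. Each function accepts a
#' `protein_records` data frame or a character vector of sequences and
#' returns a numeric matrix with one row per sequence (rownames = ids)
#' and stable, named columns.
#'
#' @param records A `protein_records` data frame (see [read_fasta()]) or a
#'   character vector of amino-acid sequences.
#' @param table A `property_group_table`; defaults to
#'   [default_property_groups()].
NULL

# Integer-encode one sequence against AA_ALPHABET; errors on anything the
# validation in protein_records() would have rejected.
encode_sequence <- function(seq, id = "?") {
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (length(idx) == 0L) {
    stop("empty sequence for record '", id, "'", call. = FALSE)
  }
  if (anyNA(idx)) {
    stop(
      "sequence '", id, "' contains residues outside the 20-letter ",
      "alphabet; read it with read_fasta() or protein_records() first",
      call. = FALSE
    )
  }
  idx
}

feature_rows <- function(records, ncol_out, colnames_out, fun) {
  seqs <- as_sequences(records)
  out <- matrix(0, nrow = length(seqs), ncol = ncol_out,
    dimnames = list(names(seqs), colnames_out)
  )
  for (i in seq_along(seqs)) {
    out[i, ] <- fun(encode_sequence(seqs[[i]], names(seqs)[i]))
  }
  out
}

#' @describeIn ctd-features 20-dimensional residue composition; rows sum
#'   to 1.
#' @return A numeric matrix, rows = sequences, columns = features.
#' @export
aa_composition <- function(records) {
  feature_rows(
    records, 20L, paste0("comp_", AA_ALPHABET),
    function(idx) tabulate(idx, nbins = 20L) / length(idx)
  )
}

content_names <- function(table) {
  unlist(lapply(table, function(p) {
    paste0("cont_", p$code, "_", names(p$groups))
  }))
}

#' @describeIn ctd-features 24-dimensional group content.
#' @export
ctd_content <- function(records, table = default_property_groups()) {
  gim <- group_index_matrix(table)
  np <- nrow(gim)
  feature_rows(
    records, 3L * np, content_names(table),
    function(idx) {
      L <- length(idx)
      as.vector(vapply(
        seq_len(np),
        function(p) tabulate(gim[p, idx], nbins = 3L) / L,
        numeric(3)
      ))
    }
  )
}

transition_names <- function(table) {
  unlist(lapply(table, function(p) {
    gn <- names(p$groups)
    paste0(
      "tran_", p$code, "_",
      c(
        paste0(gn[1], ".", gn[2]),
        paste0(gn[1], ".", gn[3]),
        paste0(gn[2], ".", gn[3])
      )
    )
  }))
}

#' @describeIn ctd-features 24-dimensional bivalent transition frequency.
#'   A single-residue sequence has no adjacent pairs; all its transition
#'   features are 0 and a warning is raised.
#' @export
ctd_transition <- function(records, table = default_property_groups()) {
  gim <- group_index_matrix(table)
  np <- nrow(gim)
  feature_rows(
    records, 3L * np, transition_names(table),
    function(idx) {
      L <- length(idx)
      if (L < 2L) {
        warning("sequence of length 1: transition features set to 0",
          call. = FALSE
        )
        return(numeric(3L * np))
      }
      a <- idx[-L]
      b <- idx[-1L]
      as.vector(vapply(seq_len(np), function(p) {
        ga <- gim[p, a]
        gb <- gim[p, b]
        lo <- pmin(ga, gb)
        hi <- pmax(ga, gb)
        c(
          sum(lo == 1L & hi == 2L),
          sum(lo == 1L & hi == 3L),
          sum(lo == 2L & hi == 3L)
        ) / L
      }, numeric(3)))
    }
  )
}

distribution_names <- function(table) {
  qs <- c("first", "q25", "q50", "q75", "q100")
  unlist(lapply(table, function(p) {
    as.vector(t(outer(names(p$groups), qs, function(g, q) {
      paste0("dist_", p$code, "_", g, "_", q)
    })))
  }))
}

#' @describeIn ctd-features 120-dimensional chain-fraction distribution.
#' @export
ctd_distribution <- function(records, table = default_property_groups()) {
  gim <- group_index_matrix(table)
  np <- nrow(gim)
  feature_rows(
    records, 15L * np, distribution_names(table),
    function(idx) {
      L <- length(idx)
      out <- numeric(15L * np)
      j <- 0L
      for (p in seq_len(np)) {
        gidx <- gim[p, idx]
        for (g in 1:3) {
          pos <- which(gidx == g)
          ng <- length(pos)
          if (ng > 0L) {
            out[j + 1:5] <- pos[c(1L, ceiling(c(0.25, 0.5, 0.75, 1) * ng))] / L
          }
          j <- j + 5L
        }
      }
      out
    }
  )
}

#' Extract a named feature matrix from protein records
#'
#' Assembles one of the package's feature sets:
#' `"distribution120"` (the 120-dimensional core used for classification),
#' `"composition20"`, `"content24"`, `"transition24"`, or `"full188"` —
#' the concatenation, in order, of composition (20), content (24),
#' transition (24) and distribution (120). Column names and order are
#' stable across calls for a given property-group table.
#'
#' @inheritParams ctd-features
#' @param feature_set One of `"distribution120"`, `"full188"`,
#'   `"composition20"`, `"content24"`, `"transition24"`.
#' @return Numeric matrix, one row per record, rownames = record ids.
#' @examples
#' recs <- protein_records("p1", "ACDEFGHIKLMNPQRSTVWY")
#' dim(extract_features(recs, "distribution120"))
#' dim(extract_features(recs, "full188"))
#' @export
extract_features <- function(records,
                             feature_set = c(
                               "distribution120", "full188",
                               "composition20", "content24",
                               "transition24"
                             ),
                             table = default_property_groups()) {
  feature_set <- match.arg(feature_set)
  switch(feature_set,
    composition20 = aa_composition(records),
    content24 = ctd_content(records, table),
    transition24 = ctd_transition(records, table),
    distribution120 = ctd_distribution(records, table),
    full188 = cbind(
      aa_composition(records),
      ctd_content(records, table),
      ctd_transition(records, table),
      ctd_distribution(records, table)
    )
  )
}

#' Write a feature matrix to CSV
#'
#' Writes an id column plus one named column per feature. The file can be
#' read back with [read_feature_matrix()].
#'
#' @param features Numeric matrix from [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(
    id = rownames(features), features,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path CSV path with an `id` column and numeric feature columns.
#' @return Numeric matrix with rownames from the id column.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  rownames(m) <- df$id
  m
}
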