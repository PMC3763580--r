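#' Generate labelled synthetic protein sequences
#'
#' Produces two sequence classes that differ only in residue-group usage:
#' negatives are i.i.d. uniform over the 20-letter alphabet, while
#' positives place an extra probability mass `bias` on `biased_set`
#' (spread uniformly within it) and the remaining `1 - bias` uniformly
#' over the whole alphabet. The default biased set is the secondary-
#' structure helix group \{E,A,L,M,Q,K,R,H\}, so the classes separate in
#' exactly the feature space the package extracts. Lengths are uniform on
#' `length_range`. Output is fully determined by `seed`.
#'
#' The generator targets feature-space separability only: it does not
#' emulate motifs, domains or any other structure of real protein
#' families.
#'
#' @param n_pos,n_neg Number of positive / negative sequences.
#' @param length_range Integer interval of sequence lengths (min 10).
#' @param bias Excess probability mass on `biased_set`, in `[0, 1]`;
#'   `bias = 0` makes the classes distributionally identical.
#' @param biased_set Residues favoured in positives.
#' @param seed Integer seed.
#' @return List with `positive` and `negative` (`protein_records`),
#'   `records` (both, positives first) and `labels` (data frame `id`,
#'   `label` with factor levels `c("neg", "pos")`).
#' @examples
#' fx <- generate_sequences(5, 5, bias = 0.5, seed = 42)
#' fx$records$id
#' @export
generate_sequences <- function(n_pos, n_neg,
                               length_range = c(50L, 200L),
                               bias = 0.5,
                               biased_set = c(
                                 "E", "A", "L", "M",
                                 "Q", "K", "R", "H"
                               ),
                               seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L)
  if (bias < 0 || bias > 1) {
    stop("bias must be in [0, 1], got ", bias, call. = FALSE)
  }
  if (length_range[1] < 10L || length_range[1] > length_range[2]) {
    stop("length_range must satisfy 10 <= min <= max", call. = FALSE)
  }
  if (!all(biased_set %in% AA_ALPHABET)) {
    stop("biased_set contains non-canonical residues", call. = FALSE)
  }

  p_pos <- rep((1 - bias) / 20, 20)
  p_pos[match(biased_set, AA_ALPHABET)] <-
    p_pos[match(biased_set, AA_ALPHABET)] + bias / length(biased_set)
  p_neg <- rep(1 / 20, 20)

  draw <- function(n, prefix, prob) {
    lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = prob),
        collapse = ""
      )
    }, "")
    protein_records(sprintf("%s_%04d", prefix, seq_len(n)), seqs)
  }

  with_seed(seed, {
    pos <- draw(n_pos, "pos", p_pos)
    neg <- draw(n_neg, "neg", p_neg)
    records <- rbind(pos, neg)
    class(records) <- c("protein_records", "data.frame")
    list(
      positive = pos,
      negative = neg,
      records = records,
      labels = data.frame(
        id = records$id,
        label = factor(rep(c("pos", "neg"), c(n_pos, n_neg)),
          levels = c("neg", "pos")
        ),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Write a label table as 2-column TSV
#'
#' Counterpart of [read_labels()]: writes `id<TAB>label` with a header
#' row.
#'
#' @param labels Data frame with columns `id` and `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(id = labels$id, label = as.character(labels$label)),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
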