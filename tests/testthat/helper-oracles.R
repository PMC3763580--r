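# Independent brute-force oracles for the four feature families.
# Deliberately written with explicit position-by-position loops and no
# shared code with the package internals, so agreement is evidence of
# correctness rather than of shared bugs.

ORACLE_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

oracle_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

oracle_composition <- function(seq) {
  chars <- oracle_chars(seq)
  out <- numeric(20)
  for (i in 1:20) {
    cnt <- 0
    for (ch in chars) {
      if (ch == ORACLE_ALPHABET[i]) cnt <- cnt + 1
    }
    out[i] <- cnt / length(chars)
  }
  out
}

oracle_group_of <- function(ch, prop) {
  for (g in 1:3) {
    if (ch %in% prop$groups[[g]]) {
      return(g)
    }
  }
  stop("residue not in any group")
}

oracle_content <- function(seq, table) {
  chars <- oracle_chars(seq)
  out <- numeric(0)
  for (prop in table) {
    for (g in 1:3) {
      cnt <- 0
      for (ch in chars) {
        if (oracle_group_of(ch, prop) == g) cnt <- cnt + 1
      }
      out <- c(out, cnt / length(chars))
    }
  }
  out
}

oracle_transition <- function(seq, table) {
  chars <- oracle_chars(seq)
  L <- length(chars)
  out <- numeric(0)
  for (prop in table) {
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      cnt <- 0
      if (L >= 2) {
        for (i in 1:(L - 1)) {
          g1 <- oracle_group_of(chars[i], prop)
          g2 <- oracle_group_of(chars[i + 1], prop)
          if ((g1 == pair[1] && g2 == pair[2]) ||
            (g1 == pair[2] && g2 == pair[1])) {
            cnt <- cnt + 1
          }
        }
      }
      out <- c(out, cnt / L)
    }
  }
  out
}

oracle_distribution <- function(seq, table) {
  chars <- oracle_chars(seq)
  L <- length(chars)
  out <- numeric(0)
  for (prop in table) {
    for (g in 1:3) {
      positions <- integer(0)
      for (i in seq_len(L)) {
        if (oracle_group_of(chars[i], prop) == g) {
          positions <- c(positions, i)
        }
      }
      n_g <- length(positions)
      if (n_g == 0) {
        out <- c(out, rep(0, 5))
      } else {
        ks <- c(
          1, ceiling(0.25 * n_g), ceiling(0.5 * n_g),
          ceiling(0.75 * n_g), ceiling(1.0 * n_g)
        )
        out <- c(out, positions[ks] / L)
      }
    }
  }
  out
}

random_sequence <- function(L) {
  paste(sample(ORACLE_ALPHABET, L, replace = TRUE), collapse = "")
}
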