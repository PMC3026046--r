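# Independent oracles and small fixture builders used across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_pocket <- function(n = 1) {
  vapply(seq_len(n), function(i)
    paste(sample(AA20, 18, replace = TRUE), collapse = ""), character(1))
}

random_ligand <- function(n = 1) {
  vapply(seq_len(n), function(i)
    paste(sample(AA20, 5, replace = TRUE), collapse = ""), character(1))
}

# Dense random lookup table in long format (independent of the package's
# internal representation)
random_weights_df <- function(n_pairs = 6, entries_per_pair = 30) {
  pairs <- unique(data.frame(
    pocket_pos = sample(1:18, n_pairs * 2, replace = TRUE),
    ligand_pos = sample(0:-4, n_pairs * 2, replace = TRUE)))
  pairs <- pairs[seq_len(min(n_pairs, nrow(pairs))), ]
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
    combos <- expand.grid(pocket_aa = AA20, ligand_aa = AA20,
                          stringsAsFactors = FALSE)
    combos <- combos[sample(nrow(combos), entries_per_pair), ]
    data.frame(pocket_pos = pairs$pocket_pos[p],
               ligand_pos = pairs$ligand_pos[p],
               pocket_aa = combos$pocket_aa, ligand_aa = combos$ligand_aa,
               weight = stats::rnorm(entries_per_pair))
  }))
}

# Brute-force psi: explicit double loop over contact pairs and the long
# weight table, no matrix indexing
psi_oracle_long <- function(pocket, ligand, weights_df, intercept = 0) {
  p <- strsplit(pocket, "")[[1]]
  l <- strsplit(ligand, "")[[1]]
  total <- intercept
  for (r in seq_len(nrow(weights_df))) {
    i <- weights_df$pocket_pos[r]
    j <- weights_df$ligand_pos[r]
    if (p[i] == weights_df$pocket_aa[r] && l[5 + j] == weights_df$ligand_aa[r]) {
      total <- total + weights_df$weight[r]
    }
  }
  total
}

# Brute-force psi over a pdz_lookup object: scalar double loop with
# name-based indexing (independent of the vectorised engine)
psi_oracle <- function(pocket, ligand, table) {
  p <- strsplit(pocket, "")[[1]]
  l <- strsplit(ligand, "")[[1]]
  total <- table$intercept
  for (k in seq_len(nrow(table$pairs))) {
    W <- table$W[[k]]
    pr <- p[table$pairs$pocket_pos[k]]
    lr <- l[5 + table$pairs$ligand_pos[k]]
    if (!pr %in% rownames(W)) pr <- "X"
    if (!lr %in% colnames(W)) lr <- "X"
    total <- total + W[pr, lr]
  }
  total
}

BLOSUM62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Global affine-gap alignment oracle (Gotoh), matching the Biostrings
# convention that a gap of length L costs gapOpening + L * gapExtension.
# Returns the query position aligned to each reference position (NA for
# a gap in the query).
nw_align_map <- function(ref, qry, sub = BLOSUM62,
                         gap_open = 11, gap_ext = 1) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(qry, "")[[1]]
  n <- length(r)
  m <- length(q)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # r[i] aligned to q[j]
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in query (ref consumed)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in ref (query consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -gap_open - (i - 1) * gap_ext
  for (j in 2:(m + 1)) Iy[1, j] <- -gap_open - (j - 1) * gap_ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[r[i - 1], q[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, Ix[i - 1, j] - gap_ext)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
    }
  }
  # traceback, preferring matches on ties
  map <- rep(NA_integer_, n)
  i <- n + 1
  j <- m + 1
  state <- which.max(c(M[i, j], Ix[i, j], Iy[i, j]))
  while (i > 1 || j > 1) {
    if (state == 1) {
      map[i - 1] <- j - 1
      s <- sub[r[i - 1], q[j - 1]]
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1
      j <- j - 1
    } else if (state == 2) {
      opts <- c(M[i - 1, j] - gap_open - gap_ext, NEG, Ix[i - 1, j] - gap_ext)
      state <- if (opts[1] >= opts[3]) 1 else 2
      i <- i - 1
    } else {
      opts <- c(M[i, j - 1] - gap_open - gap_ext, Iy[i, j - 1] - gap_ext)
      state <- if (opts[1] >= opts[2]) 1 else 3
      j <- j - 1
    }
    if (i == 1 && j > 1 && state == 1) state <- 3
    if (j == 1 && i > 1 && state == 1) state <- 2
  }
  map
}

# pocket read off the oracle's alignment map
oracle_pocket <- function(ref, qry, columns, ...) {
  map <- nw_align_map(ref, qry, ...)
  q <- strsplit(qry, "")[[1]]
  idx <- map[columns]
  paste(ifelse(is.na(idx), "-", q[idx]), collapse = "")
}

# small interaction-set builder
make_calls <- function(sets) {
  do.call(rbind, lapply(names(sets), function(d) {
    if (length(sets[[d]]) == 0) return(NULL)
    data.frame(domain_id = d, ligand_id = sets[[d]], psi = 1,
               stringsAsFactors = FALSE)
  }))
}
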