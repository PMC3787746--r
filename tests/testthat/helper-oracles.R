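# Independent oracles used across the suite.  These deliberately avoid the
# package's own table machinery: translation comes from seqinr, pathway
# enumeration and dynamic programming are written from scratch.

# translate one codon with seqinr ("*" for stop)
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(tolower(codon), "")[[1]])
}

# NG86 synonymous site count of one codon (changes to stops count as
# nonsynonymous so sites sum to 3)
oracle_syn_sites <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(codon, pos, pos) == b) next
      alt <- codon
      substr(alt, pos, pos) <- b
      if (oracle_translate(alt) != "*" && oracle_translate(alt) == aa)
        s <- s + 1 / 3
    }
  }
  s
}

# pathway-averaged (Sd, Nd) between two sense codons; minimal pathways
# through stop codons are excluded
oracle_pair_diffs <- function(c1, c2) {
  dpos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(dpos) == 0) return(c(0, 0))
  perms <- list(`1` = list(1), `2` = list(1:2, 2:1),
                `3` = list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                           c(2, 3, 1), c(3, 1, 2), c(3, 2, 1)))
  tot <- c(0, 0); nvalid <- 0
  for (ord in perms[[as.character(length(dpos))]]) {
    cur <- c1; sd <- 0; nd <- 0; ok <- TRUE
    for (pos in dpos[ord]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (oracle_translate(nxt) == "*") { ok <- FALSE; break }
      if (oracle_translate(cur) == oracle_translate(nxt)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { tot <- tot + c(sd, nd); nvalid <- nvalid + 1 }
  }
  tot / nvalid
}

# full affine-gap DP, scores only, same conventions as the implementation:
# gap of length L costs open + extend*(L-1); pattern global, subject
# free-ended ("glocal") or fully local
oracle_affine_score <- function(pattern, subject, match, mismatch, open,
                                extend, mode = c("glocal", "local")) {
  mode <- match.arg(mode)
  p <- strsplit(pattern, "")[[1]]; s <- strsplit(subject, "")[[1]]
  m <- length(p); n <- length(s)
  NEG <- -1e30
  M <- matrix(NEG, m + 1, n + 1); X <- M; Y <- M
  M[1, ] <- 0
  if (m >= 1) X[2:(m + 1), 1] <- -(open + extend * (0:(m - 1)))
  if (mode == "local") M[, 1] <- 0
  for (i in 1:m) {
    for (j in 1:n) {
      sc <- if (p[i] == s[j] && p[i] != "N") match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
      if (mode == "local") M[i + 1, j + 1] <- max(M[i + 1, j + 1], 0)
      X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - extend,
                             Y[i, j + 1] - open)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open, Y[i + 1, j] - extend,
                             X[i + 1, j] - open)
    }
  }
  if (mode == "local") max(M) else max(M[m + 1, ], X[m + 1, ])
}

# random in-frame CDS with ATG start, no internal stops, one terminal stop
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                  c("T", "C", "A", "G")), 1, paste,
                      collapse = "")
  sense <- setdiff(all_codons, stops)
  paste0(paste(c("ATG", sample(sense, n_codons - 1, TRUE)), collapse = ""),
         sample(stops, 1))
}

uniform_pi <- rep(1 / 61, 61)

# quick two-row alignment simulated under the GY94 process
sim_pair_aln <- function(n_codons, t, kappa, omega, pi = uniform_pi,
                         gene_id = "gene") {
  anc <- sample.int(61, n_codons, TRUE, prob = pi)
  ev <- omegascan:::simulate_gy94_branch(anc, t, kappa, omega, pi)
  codon_aln(rbind(anc, ev$states), c("a", "b"), gene_id)
}
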