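# Fixtures are generated in code; nothing binary ships with the tests.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# deterministic "different base" map, used to force mismatching flanks
other_base <- function(b) chartr("ACGT", "CAGT", chartr("GT", "TG", b))

# a shared small synthetic circular mitochondrial reference
fixture_mito <- function() synthetic_mito_genome(seed = 2011L)

# Implant an exact copy of mito[m_start, m_end) at 0-based position `at`
# of a random background, forcing ~8 flanking bases on each side to
# mismatch the circular continuation of the mitochondrial sequence so the
# optimal local alignment is exactly the implant.
implant_exact <- function(mito, m_start, m_end, chrom_len, at, seed = 1L) {
  set.seed(seed)
  L <- nchar(mito$sequence)
  bg <- rand_dna(chrom_len)
  frag <- substr(mito$sequence, m_start + 1L, m_end)
  substr(bg, at + 1L, at + nchar(frag)) <- frag
  for (k in 1:8) {
    pos <- at - k                     # left flank, mito base m_start - k
    mi <- (m_start - k) %% L
    if (pos >= 0) {
      mb <- substr(mito$sequence, mi + 1L, mi + 1L)
      substr(bg, pos + 1L, pos + 1L) <- other_base(mb)
    }
    pos2 <- at + nchar(frag) + k - 1L # right flank, mito base m_end + k - 1
    mi2 <- (m_end + k - 1L) %% L
    if (pos2 < chrom_len) {
      mb2 <- substr(mito$sequence, mi2 + 1L, mi2 + 1L)
      substr(bg, pos2 + 1L, pos2 + 1L) <- other_base(mb2)
    }
  }
  sequence_record("chr1", bg)
}

# one-row HSP for merge-rule tests
mk_hsp <- function(chrom = "chr1", nuc_start, nuc_end, strand = "+",
                   mito_start, mito_end, identity = 95, id = "h") {
  hsp_table(chrom = chrom, nuc_start = nuc_start, nuc_end = nuc_end,
            strand = strand, mito_start = mito_start, mito_end = mito_end,
            percent_identity = identity,
            alignment_length = nuc_end - nuc_start, hsp_id = id)
}

# random HSP sets for assembly property tests
random_hsps <- function(n, L = 16569L, chroms = c("chr1", "chr2"),
                        max_pos = 60000L) {
  nuc_len <- sample(50:2500, n, replace = TRUE)
  mito_len <- pmin(nuc_len, L - 1L)
  mito_start <- vapply(mito_len, function(l) sample(0:(L - l), 1L),
                       integer(1L))
  nuc_start <- sample(0:max_pos, n, replace = TRUE)
  hsp_table(chrom = sample(chroms, n, replace = TRUE),
            nuc_start = nuc_start, nuc_end = nuc_start + nuc_len,
            strand = sample(c("+", "-"), n, replace = TRUE),
            mito_start = mito_start, mito_end = mito_start + mito_len,
            percent_identity = runif(n, 63, 100),
            alignment_length = nuc_len)
}

# independent assembly oracle: connected components of the full pairwise
# mergeable() graph, via igraph
oracle_partition <- function(hsps, params = assembly_params()) {
  n <- nrow(hsps)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && hsps$chrom[i] == hsps$chrom[j]) {
      a <- hsps[i, ]; b <- hsps[j, ]
      if (a$nuc_start > b$nuc_start) { tmp <- a; a <- b; b <- tmp }
      adj[i, j] <- adj[j, i] <- mergeable(a, b, params)
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

same_partition <- function(m1, key1, m2, key2) {
  s1 <- lapply(split(key1, m1), sort)
  s2 <- lapply(split(key2, m2), sort)
  setequal(s1, s2)
}

blast_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = TRUE)
}

# Smith-Waterman / Needleman-Wunsch oracle scores via Biostrings
sw_oracle <- function(query, subject, type = "local") {
  Biostrings::pairwiseAlignment(pattern = query, subject = subject,
                                type = type,
                                substitutionMatrix = blast_submat(),
                                gapOpening = 5, gapExtension = 2)
}

# Build a target sequence by inserting segments into a source, returning
# the exact per-position correspondence as an oracle. Inserted bases are
# chosen to differ from both neighbours so the optimal alignment places
# each gap unambiguously.
make_insertion_pair <- function(src_len = 1000L, ins_after, ins_len) {
  src <- rand_dna(src_len)
  pieces <- character(0)
  prev <- 0L
  target_of <- integer(src_len) # oracle: source pos -> target pos
  offset <- 0L
  for (k in seq_along(ins_after)) {
    pieces <- c(pieces, substr(src, prev + 1L, ins_after[k]))
    left <- substr(src, ins_after[k], ins_after[k])
    right <- substr(src, ins_after[k] + 1L, ins_after[k] + 1L)
    ins <- paste(rep(setdiff(c("A", "C", "G", "T"), c(left, right))[1L],
                     ins_len[k]), collapse = "")
    pieces <- c(pieces, ins)
    target_of[(prev + 1L):ins_after[k]] <- (prev:(ins_after[k] - 1L)) + offset
    offset <- offset + ins_len[k]
    prev <- ins_after[k]
  }
  pieces <- c(pieces, substr(src, prev + 1L, src_len))
  target_of[(prev + 1L):src_len] <- (prev:(src_len - 1L)) + offset
  list(source = sequence_record("src", src),
       target = sequence_record("tgt", paste(pieces, collapse = "")),
       target_of = target_of) # target_of[p + 1] lifts 0-based position p
}
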