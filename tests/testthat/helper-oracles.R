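# Independent brute-force oracles and fixture builders used across tests.
# Each oracle is written from the definition, not from the package code.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# Position-by-position Hamming scan for a motif.
naive_motif_scan <- function(sequence, motif, max_mismatch) {
  k <- nchar(motif)
  n <- nchar(sequence)
  hits <- list()
  for (p in seq_len(max(0, n - k + 1))) {
    window <- substr(sequence, p, p + k - 1)
    mm <- sum(strsplit(window, "")[[1]] != strsplit(motif, "")[[1]])
    if (mm <= max_mismatch) {
      hits[[length(hits) + 1]] <- data.frame(position = p, mismatches = mm)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(position = integer(), mismatches = integer()))
  }
  do.call(rbind, hits)
}

# Enumerate every upstream position, test codon, frame, and intervening
# in-frame stops one codon at a time.
naive_uatg_scan <- function(sequence, main_start) {
  stops <- c("TAA", "TAG", "TGA")
  out <- integer(0)
  for (p in seq_len(main_start - 1)) {
    if (substr(sequence, p, p + 2) != "ATG") next
    if ((main_start - p) %% 3 != 0) next
    blocked <- FALSE
    q <- p + 3
    while (q < main_start) {
      if (substr(sequence, q, q + 2) %in% stops) blocked <- TRUE
      q <- q + 3
    }
    if (!blocked) out <- c(out, p)
  }
  out
}

# Recount the 2x2 table directly from the label vectors.
naive_confusion <- function(groups, calls) {
  c(a = sum(groups == "stressed" & calls == "positive"),
    b = sum(groups == "control" & calls == "positive"),
    c = sum(groups == "stressed" & calls == "negative"),
    d = sum(groups == "control" & calls == "negative"))
}

# N-X(not P)-S/T triplet scan by explicit enumeration.
naive_nglyc_scan <- function(sequence) {
  out <- integer(0)
  for (i in seq_len(max(0, nchar(sequence) - 2))) {
    tri <- strsplit(substr(sequence, i, i + 2), "")[[1]]
    if (tri[1] == "N" && tri[2] != "P" && tri[3] %in% c("S", "T")) {
      out <- c(out, i)
    }
  }
  out
}

# The published exon coordinate set of the seabass BDNF gene.
table4_exons <- function() {
  data.frame(
    name = c("1beta", "1a", "1b", "1c", "1d", "2"),
    start = c(321, 1367, 4270, 8347, 11540, 14063),
    end = c(602, 1818, 4315, 8646, 11797, 15130)
  )
}

# A synthetic 299-residue seabass-mode BDNF precursor: 20-aa signal,
# 150-aa propeptide ending in a furin site (RVRR, cleaved after residue
# 170), 129-aa mature domain with an N-glycosylation sequon, and no SKI-1
# RGLT motif anywhere. Deterministic; clearly synthetic, not the deposited
# FJ711591 sequence.
synthetic_seabass_precursor <- function() {
  set.seed(4242)
  safe <- c("A", "S", "T", "V", "L", "I", "E", "D", "K", "Q", "F", "Y", "H")
  signal <- paste0("M", paste(sample(safe, 19, replace = TRUE), collapse = ""))
  pro_body <- paste(sample(safe, 146, replace = TRUE), collapse = "")
  propeptide <- paste0(pro_body, "RVRR")
  mature_body <- paste(sample(safe, 121, replace = TRUE), collapse = "")
  mature <- paste0("HSDP", mature_body, "NAST")  # sequon NAS near C-terminus
  paste0(signal, propeptide, mature)
}
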