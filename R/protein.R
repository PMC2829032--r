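#' Construct a validated protein sequence
#'
#' @param residues Amino-acid string using the 20 standard one-letter codes;
#'   lower case is accepted and normalised.
#' @param id Identifier label.
#' @return A list of class `protein_sequence` with `residues` and `id`.
#' @export
#' @examples
#' protein_sequence("MTILFLTMVISYFGCMKA", id = "demo")
protein_sequence <- function(residues, id = "protein") {
  if (!is.character(residues) || length(residues) != 1 || is.na(residues) ||
      nchar(residues) == 0) {
    abort("`residues` must be a single non-empty string.",
          class = "probdnf_residue_error")
  }
  residues <- toupper(residues)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", residues)) {
    abort("`residues` contains non-standard amino-acid codes.",
          class = "probdnf_residue_error")
  }
  structure(list(residues = residues, id = id), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence %s: %d aa>\n", x$id, nchar(x$residues)))
  invisible(x)
}

as_residues <- function(protein) {
  if (inherits(protein, "protein_sequence")) {
    protein$residues
  } else {
    protein_sequence(as.character(protein))$residues
  }
}

#' Find the SKI-1 (MBTPS1) cleavage motif
#'
#' SKI-1 cleaves the mammalian BDNF precursor after the threonine of an
#' `RGLT` motif (Thr57), producing the pro28K intermediate. The motif is
#' absent from teleost proBDNF, so `NULL` is the expected result for fish
#' sequences: they present only the full precursor and the mature form.
#'
#' @param protein A [protein_sequence()] or amino-acid string.
#' @return A one-row tibble (`protease`, `cleave_after`, `motif`) for the
#'   leftmost `RGLT` occurrence, or `NULL` when the motif is absent.
#' @export
#' @examples
#' find_ski1_site("AAARGLTAA")$cleave_after  # 7
#' is.null(find_ski1_site("AAAAAA"))         # TRUE: teleost-style precursor
find_ski1_site <- function(protein) {
  res <- as_residues(protein)
  hit <- regexpr("RGLT", res, fixed = TRUE)
  if (hit == -1) return(NULL)
  tibble(protease = "SKI-1",
         cleave_after = as.integer(hit + 3),
         motif = "RGLT")
}

#' Find the minimal furin cleavage motif
#'
#' Furin, the proprotein convertase that matures BDNF intracellularly,
#' recognises the minimal consensus R-X-[KR]-R and cleaves after the final
#' arginine. The leftmost match wins; overlapping matches further right are
#' ignored.
#'
#' @inheritParams find_ski1_site
#' @param search_window Optional length-2 integer vector `c(from, to)`
#'   restricting the search to matches that start within the window.
#' @return A one-row tibble (`protease`, `cleave_after`, `motif`) or `NULL`.
#' @export
#' @examples
#' find_furin_site("AAARVRRHSDA")$cleave_after  # 7, after RVRR
find_furin_site <- function(protein, search_window = NULL) {
  res <- as_residues(protein)
  from <- 1L
  to <- nchar(res)
  if (!is.null(search_window)) {
    stopifnot(length(search_window) == 2, search_window[1] <= search_window[2])
    from <- max(1L, as.integer(search_window[1]))
    to <- min(to, as.integer(search_window[2]))
  }
  # match must start within the window; perl lookahead not needed for a
  # leftmost single match
  sub <- substr(res, from, nchar(res))
  hit <- regexpr("R.[KR]R", sub)
  if (hit == -1) return(NULL)
  start <- from + as.integer(hit) - 1L
  if (start > to) return(NULL)
  tibble(protease = "furin",
         cleave_after = start + 3L,
         motif = substr(res, start, start + 3L))
}

#' Partition a BDNF precursor into signal, propeptide and mature segments
#'
#' The neurotrophin precursor is organised as a short N-terminal signal
#' peptide, a central propeptide, and the mature C-terminal growth factor.
#' The signal length and the mature start are inputs (signal peptides are
#' annotated or predicted externally, and the mature start is the residue
#' after the convertase cleavage site).
#'
#' @inheritParams find_ski1_site
#' @param signal_length Number of N-terminal residues in the signal peptide.
#' @param mature_start 1-based index of the first residue of the mature
#'   protein; must exceed `signal_length` and lie within the sequence.
#' @return A list of class `precursor_partition` with character segments
#'   `signal`, `propeptide`, `mature`; their concatenation reproduces the
#'   input precursor.
#' @export
#' @examples
#' p <- partition_precursor(strrep("A", 299), signal_length = 20,
#'                          mature_start = 171)
#' vapply(p[c("signal", "propeptide", "mature")], nchar, 1L)  # 20 150 129
partition_precursor <- function(protein, signal_length, mature_start) {
  res <- as_residues(protein)
  n <- nchar(res)
  signal_length <- assert_count(signal_length, "signal_length")
  mature_start <- assert_count(mature_start, "mature_start")
  if (!(signal_length > 0 && signal_length < mature_start && mature_start <= n)) {
    abort("Need 0 < signal_length < mature_start <= sequence length.",
          class = "probdnf_partition_error")
  }
  if (mature_start - 1 == signal_length) {
    abort("Propeptide segment would be empty (mature_start == signal_length + 1).",
          class = "probdnf_partition_error")
  }
  structure(
    list(
      signal = substr(res, 1, signal_length),
      propeptide = substr(res, signal_length + 1, mature_start - 1),
      mature = substr(res, mature_start, n)
    ),
    class = "precursor_partition"
  )
}

#' @export
print.precursor_partition <- function(x, ...) {
  cat(sprintf("<precursor_partition: signal %d aa | propeptide %d aa | mature %d aa>\n",
              nchar(x$signal), nchar(x$propeptide), nchar(x$mature)))
  invisible(x)
}

# Average residue masses (Da), standard reference values; a peptide's mass
# is the residue sum plus one water.
AVERAGE_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS_DA <- 18.0153

#' Average molecular weight of a protein in kilodaltons
#'
#' Sum of average residue masses plus one water, matching the "calculated
#' Mw" convention used to interpret gel-apparent band sizes (proBDNF about
#' 28.7 kDa, mature BDNF about 13.3 kDa in seabass).
#'
#' @inheritParams find_ski1_site
#' @return Mass in kDa (numeric scalar). Use `round(x, 1)` for the one
#'   decimal conventionally reported.
#' @export
#' @examples
#' molecular_weight("G")   # 0.0750672
#' molecular_weight("GG")  # 0.1321191
molecular_weight <- function(protein) {
  res <- as_residues(protein)
  aa <- strsplit(res, "")[[1]]
  (sum(AVERAGE_RESIDUE_MASS[aa]) + WATER_MASS_DA) / 1000
}

#' Scan for N-glycosylation sequons
#'
#' Reports every N-X-S/T sequon (X any residue except proline), the
#' canonical acceptor site for N-linked glycosylation.
#'
#' @inheritParams find_ski1_site
#' @return Integer vector of 1-based positions of the asparagine of each
#'   sequon, in order.
#' @export
#' @examples
#' scan_nglyc_sites("ANGTA")  # 2
#' scan_nglyc_sites("ANPTA")  # integer(0)
scan_nglyc_sites <- function(protein) {
  res <- as_residues(protein)
  n <- nchar(res)
  if (n < 3) return(integer(0))
  aa <- strsplit(res, "")[[1]]
  i <- seq_len(n - 2)
  which_ok <- aa[i] == "N" & aa[i + 1] != "P" & (aa[i + 2] == "S" | aa[i + 2] == "T")
  as.integer(i[which_ok])
}

#' Report cleavage sites and sequons for a precursor
#'
#' Convenience wrapper running [find_ski1_site()], [find_furin_site()] and
#' [scan_nglyc_sites()] over one sequence and returning a tidy site table.
#'
#' @inheritParams find_ski1_site
#' @return A tibble with columns `type`, `position`, `detail`; zero rows if
#'   nothing is found.
#' @export
scan_precursor_sites <- function(protein) {
  res <- as_residues(protein)
  out <- list()
  ski <- find_ski1_site(res)
  if (!is.null(ski)) {
    out[[length(out) + 1]] <- tibble(type = "SKI-1",
                                     position = ski$cleave_after,
                                     detail = ski$motif)
  }
  fur <- find_furin_site(res)
  if (!is.null(fur)) {
    out[[length(out) + 1]] <- tibble(type = "furin",
                                     position = fur$cleave_after,
                                     detail = fur$motif)
  }
  ng <- scan_nglyc_sites(res)
  if (length(ng) > 0) {
    out[[length(out) + 1]] <- tibble(type = "N-glyc",
                                     position = ng,
                                     detail = substring(res, ng, ng + 2))
  }
  if (length(out) == 0) {
    return(tibble(type = character(), position = integer(),
                  detail = character()))
  }
  bind_rows(out)
}

#' Translate a coding nucleotide sequence
#'
#' Standard-code translation of an open reading frame, stopping at the first
#' stop codon.
#'
#' @param cds Nucleotide string beginning at the start codon.
#' @param id Identifier for the resulting protein.
#' @return A [protein_sequence()].
#' @export
translate_cds <- function(cds, id = "translated") {
  cds <- clean_dna(as.character(cds), "cds")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, 3 * (nchar(cds) %/% 3))),
    if.fuzzy.codon = "solve"
  ))
  aa <- sub("\\*.*$", "", aa)
  protein_sequence(aa, id = id)
}
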