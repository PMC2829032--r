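#' Build a multi-5'UTR-exon gene model
#'
#' Represents a gene in which several alternative untranslated first exons
#' (a 5'UTR exon cluster) are each spliced directly onto a single coding
#' exon, forming bipartite transcripts. Coordinates are 1-based inclusive on
#' the plus strand.
#'
#' @param exons A data frame with columns `name`, `start`, `end` and
#'   optionally `is_coding` (logical). When `is_coding` is absent the exon
#'   named `"2"` is taken as the coding exon. Exons must be sorted by start,
#'   non-overlapping, with exactly one coding exon which must come last.
#' @param seqid Identifier of the reference sequence the coordinates refer
#'   to.
#' @return A tibble of class `gene_model` with columns `name`, `start`,
#'   `end`, `is_coding` and attribute `seqid`.
#' @export
#' @examples
#' gm <- gene_model(data.frame(
#'   name = c("1c", "2"), start = c(10, 200), end = c(60, 400)
#' ))
#' gene_span(gm)
gene_model <- function(exons, seqid = "unknown") {
  exons <- as_tibble(exons)
  stopifnot(all(c("name", "start", "end") %in% names(exons)))
  if (nrow(exons) < 1) {
    abort("A gene model needs at least one exon.", class = "probdnf_model_error")
  }
  if (!"is_coding" %in% names(exons)) {
    exons$is_coding <- exons$name == "2"
  }
  exons <- select(exons, "name", "start", "end", "is_coding")
  exons$name <- as.character(exons$name)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (anyDuplicated(exons$name)) {
    abort("Exon names must be unique within a model.",
          class = "probdnf_model_error")
  }
  if (any(exons$start > exons$end) || any(exons$start < 1)) {
    abort("Each exon must satisfy 1 <= start <= end.",
          class = "probdnf_model_error")
  }
  if (is.unsorted(exons$start, strictly = TRUE)) {
    abort("Exons must be sorted by increasing start.",
          class = "probdnf_model_error")
  }
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort("Exons must not overlap.", class = "probdnf_model_error")
  }
  if (sum(exons$is_coding) != 1 || !exons$is_coding[nrow(exons)]) {
    abort("A model must contain exactly one coding exon, last in order.",
          class = "probdnf_model_error")
  }
  structure(exons, seqid = seqid,
            class = c("gene_model", class(exons)))
}

#' Exon lengths in base pairs
#'
#' Length of a 1-based inclusive interval: `end - start + 1`.
#'
#' @param exon A `gene_model` or any data frame with `start` and `end`
#'   columns; vectorised over rows.
#' @return An integer vector of lengths, named by exon when names are
#'   available.
#' @export
#' @examples
#' exon_length(data.frame(name = "1beta", start = 321, end = 602))  # 282
exon_length <- function(exon) {
  stopifnot(is.data.frame(exon), all(c("start", "end") %in% names(exon)))
  len <- as.integer(exon$end - exon$start + 1)
  if ("name" %in% names(exon)) names(len) <- exon$name
  len
}

#' Genomic span of a gene model
#'
#' Distance from the first exon's start to the last exon's end, inclusive.
#'
#' @param model A [gene_model()].
#' @return Span in base pairs (integer).
#' @export
gene_span <- function(model) {
  if (!inherits(model, "gene_model")) {
    abort("`model` must be a gene_model.", class = "probdnf_model_error")
  }
  as.integer(model$end[nrow(model)] - model$start[1] + 1)
}

#' Validate GT-AG splice junctions against a genomic sequence
#'
#' Checks the canonical eukaryotic splice consensus on the two intronic
#' nucleotides flanking each exon: the intron must begin with `GT`
#' immediately after a donor exon and end with `AG` immediately before an
#' acceptor exon. The terminal exon has no donor and the initial exon no
#' acceptor.
#'
#' @param genome A nucleotide string (or `Biostrings::DNAString`) covering
#'   all exon coordinates; handled case-insensitively.
#' @param model A [gene_model()].
#' @return A tibble with one row per junction: `exon`, `role`
#'   (`"donor"`/`"acceptor"`), `position` (genomic start of the checked
#'   dinucleotide), `observed`, `valid`.
#' @export
#' @examples
#' gm <- gene_model(data.frame(name = c("1", "2"), start = c(1, 9),
#'                             end = c(4, 12)))
#' validate_splice_junctions("ACGTGTCCAGACGT", gm)
validate_splice_junctions <- function(genome, model) {
  genome <- clean_dna(as.character(genome), "genome")
  if (!inherits(model, "gene_model")) {
    abort("`model` must be a gene_model.", class = "probdnf_model_error")
  }
  n <- nrow(model)
  glen <- nchar(genome)
  if (model$end[n] + (if (n > 1) 2 else 0) > glen || model$start[1] < 1) {
    abort("Exon coordinates (plus splice context) fall outside the genome.",
          class = "probdnf_range_error")
  }
  rows <- list()
  for (i in seq_len(n)) {
    if (i < n) {
      pos <- model$end[i] + 1
      obs <- substr(genome, pos, pos + 1)
      rows[[length(rows) + 1]] <- tibble(
        exon = model$name[i], role = "donor", position = pos,
        observed = obs, valid = obs == "GT")
    }
    if (i > 1) {
      pos <- model$start[i] - 2
      if (pos < 1) {
        abort("Acceptor context before the first base of the genome.",
              class = "probdnf_range_error")
      }
      obs <- substr(genome, pos, pos + 1)
      rows[[length(rows) + 1]] <- tibble(
        exon = model$name[i], role = "acceptor", position = pos,
        observed = obs, valid = obs == "AG")
    }
  }
  bind_rows(rows)
}

#' Assemble a bipartite transcript
#'
#' Splices one of the alternative 5'UTR exons directly onto the coding exon,
#' the structure of the BDNF transcripts in teleosts: each variant shares
#' the coding region and differs only in its 5'UTR.
#'
#' @inheritParams validate_splice_junctions
#' @param five_prime_exon Name of the (non-coding) 5' exon.
#' @return A list of class `transcript_variant` with elements `name` (e.g.
#'   `"1c/2"`), `five_prime_exon`, `sequence` (spliced nucleotide string)
#'   and `junction_offset` (transcript position of the last base of the 5'
#'   exon).
#' @export
assemble_bipartite_transcript <- function(genome, model, five_prime_exon) {
  genome <- clean_dna(as.character(genome), "genome")
  if (!inherits(model, "gene_model")) {
    abort("`model` must be a gene_model.", class = "probdnf_model_error")
  }
  hit <- which(model$name == five_prime_exon)
  if (length(hit) != 1) {
    abort(sprintf("Unknown exon name '%s'.", five_prime_exon),
          class = "probdnf_lookup_error")
  }
  if (model$is_coding[hit]) {
    abort("The coding exon cannot serve as the 5' part of a bipartite transcript.",
          class = "probdnf_usage_error")
  }
  coding <- which(model$is_coding)
  if (model$end[coding] > nchar(genome)) {
    abort("Exon coordinates fall outside the genome.",
          class = "probdnf_range_error")
  }
  five_seq <- substr(genome, model$start[hit], model$end[hit])
  coding_seq <- substr(genome, model$start[coding], model$end[coding])
  structure(
    list(
      name = paste0(five_prime_exon, "/", model$name[coding]),
      five_prime_exon = five_prime_exon,
      sequence = paste0(five_seq, coding_seq),
      junction_offset = nchar(five_seq)
    ),
    class = "transcript_variant"
  )
}

#' @export
print.transcript_variant <- function(x, ...) {
  cat(sprintf("<transcript_variant %s: %d nt, 5' exon ends at %d>\n",
              x$name, nchar(x$sequence), x$junction_offset))
  invisible(x)
}

#' Scan for upstream in-frame ATG codons
#'
#' Finds alternative translation start sites upstream of the annotated main
#' start codon: positions carrying `ATG`, in frame with the main start
#' (distance divisible by 3), and with no in-frame stop codon (TAA/TAG/TGA)
#' between the candidate and the main start. Such uATGs can extend the
#' precursor's N-terminus.
#'
#' @param variant A `transcript_variant` or a nucleotide string.
#' @param main_start 1-based transcript position of the main start codon;
#'   must point at an ATG.
#' @return Integer vector of candidate start positions, ordered 5' to 3'.
#' @export
#' @examples
#' scan_upstream_inframe_atgs("ATGAAAATGCCC", main_start = 7)  # 1
scan_upstream_inframe_atgs <- function(variant, main_start) {
  seq_str <- if (inherits(variant, "transcript_variant")) {
    variant$sequence
  } else {
    as.character(variant)
  }
  seq_str <- clean_dna(seq_str, "transcript sequence")
  main_start <- assert_count(main_start, "main_start")
  if (main_start + 2 > nchar(seq_str) ||
      substr(seq_str, main_start, main_start + 2) != "ATG") {
    abort("`main_start` must point at an ATG codon within the transcript.",
          class = "probdnf_usage_error")
  }
  stops <- c("TAA", "TAG", "TGA")
  cand <- integer(0)
  p <- main_start - 3L
  blocked <- FALSE
  while (p >= 1L && !blocked) {
    codon <- substr(seq_str, p, p + 2L)
    if (codon %in% stops) {
      blocked <- TRUE
    } else {
      if (codon == "ATG") cand <- c(p, cand)
      p <- p - 3L
    }
  }
  cand
}

#' Scan for CRE consensus motifs
#'
#' Slides the canonical cAMP/calcium response element octamer `TGACGTCA`
#' along the sequence and reports every window within the allowed Hamming
#' distance. The near-consensus variant `TGAAGTCA` found upstream of BDNF
#' exon 1c is one mismatch from canonical.
#'
#' @param sequence Nucleotide string (case-insensitive), plus strand only.
#' @param max_mismatch Maximum mismatches allowed (0, 1 or 2).
#' @param motif Consensus to scan for (default `TGACGTCA`).
#' @return A tibble with columns `motif` (the matched window), `position`
#'   (1-based start), `mismatches`, `strand` (`"+"`), ordered by position.
#' @export
#' @examples
#' scan_cre_motifs("GGTGAAGTCAGG", max_mismatch = 1)
scan_cre_motifs <- function(sequence, max_mismatch = 1, motif = "TGACGTCA") {
  sequence <- clean_dna(as.character(sequence), "sequence")
  motif <- clean_dna(motif, "motif")
  if (!max_mismatch %in% 0:2) {
    abort("`max_mismatch` must be 0, 1 or 2.", class = "probdnf_usage_error")
  }
  k <- nchar(motif)
  n <- nchar(sequence)
  empty <- tibble(motif = character(), position = integer(),
                  mismatches = integer(), strand = character())
  if (n < k) return(empty)
  seq_chars <- strsplit(sequence, "")[[1]]
  motif_chars <- strsplit(motif, "")[[1]]
  n_win <- n - k + 1
  mm <- integer(n_win)
  for (j in seq_len(k)) {
    mm <- mm + (seq_chars[j:(j + n_win - 1)] != motif_chars[j])
  }
  pos <- which(mm <= max_mismatch)
  if (length(pos) == 0) return(empty)
  tibble(
    motif = substring(sequence, pos, pos + k - 1),
    position = as.integer(pos),
    mismatches = mm[pos],
    strand = "+"
  )
}

#' Read and write gene models as GFF3
#'
#' Round-trips a [gene_model()] through GFF3 (1-based inclusive, matching
#' the model's native convention) with one `gene` feature spanning the model
#' and one `exon` feature per exon; the coding exon is flagged through the
#' `is_coding` attribute.
#'
#' @param model A [gene_model()].
#' @param path GFF3 file path.
#' @return `write_gene_model_gff3()` returns `model` invisibly;
#'   `read_gene_model_gff3()` returns a `gene_model`.
#' @export
write_gene_model_gff3 <- function(model, path) {
  if (!inherits(model, "gene_model")) {
    abort("`model` must be a gene_model.", class = "probdnf_model_error")
  }
  seqid <- attr(model, "seqid")
  gr <- GenomicRanges::GRanges(
    seqnames = seqid,
    ranges = IRanges::IRanges(
      start = c(model$start[1], model$start),
      end = c(model$end[nrow(model)], model$end)
    ),
    strand = "+",
    type = c("gene", rep("exon", nrow(model))),
    Name = c("BDNF", model$name),
    is_coding = c(NA, ifelse(model$is_coding, "true", "false"))
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(model)
}

#' @rdname write_gene_model_gff3
#' @export
read_gene_model_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) {
    abort("No exon features found in the GFF3 file.",
          class = "probdnf_model_error")
  }
  exons <- tibble(
    name = as.character(ex$Name),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex)
  )
  if (!is.null(ex$is_coding)) {
    exons$is_coding <- tolower(as.character(ex$is_coding)) == "true"
  }
  gene_model(exons[order(exons$start), ],
             seqid = as.character(GenomicRanges::seqnames(ex)[1]))
}

#' The published seabass BDNF gene model
#'
#' The exon coordinate set of the *Dicentrarchus labrax* BDNF gene: five
#' alternative 5'UTR exons (1beta, 1a, 1b, 1c, 1d) and the single coding
#' exon 2, spanning roughly 15 kb. Shipped as a GFF3 fixture and loaded
#' through [read_gene_model_gff3()].
#'
#' @return A [gene_model()].
#' @export
#' @examples
#' gm <- seabass_bdnf_model()
#' exon_length(gm)
#' gene_span(gm)
seabass_bdnf_model <- function() {
  read_gene_model_gff3(
    system.file("extdata", "seabass_bdnf.gff3", package = "probdnf",
                mustWork = TRUE)
  )
}
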