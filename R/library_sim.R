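# Synthetic-data generator: assembles a barcoded plasmid library from a
# fragment pool and emits paired reads (read 1 = flanked barcode, read 2 =
# fragment) with Poisson depth, singlet inflation, per-base errors and two
# kinds of chimeras (plasmid-level heterodimers, read-level PCR template
# switches), together with a per-read ground-truth table.

#' Read simulation configuration
#'
#' @param mean_depth Poisson mean reads per clone (the optimized protocol is
#'   evaluated around 10x).
#' @param singlet_inflation expected number of spurious singleton reads per
#'   clone; each carries the clone's barcode with one forced substitution,
#'   emulating the error-borne singlets seen on top of the Poisson counts.
#' @param sub_rate,ins_rate,del_rate per-base substitution / insertion /
#'   deletion probabilities. Defaults emulate a well-behaved short-read run.
#' @param base_quality,error_quality phred assigned to correct and to
#'   error-bearing bases; errors are thereby enriched at low phred.
#' @param chimera_rate probability that a read pair links the fragment to the
#'   barcode of a different, uniformly chosen clone (PCR template switching;
#'   emulsion PCR is represented simply by a low value here).
#' @param seed optional integer seed applied at the start of simulation.
#' @return object of class \code{read_sim_config}.
#' @export
read_sim_config <- function(mean_depth = 10, singlet_inflation = 0.02,
                            sub_rate = 0.001, ins_rate = 1e-4, del_rate = 1e-4,
                            base_quality = 37L, error_quality = 12L,
                            chimera_rate = 0, seed = NULL) {
  stopifnot(mean_depth > 0, singlet_inflation >= 0,
            sub_rate >= 0, sub_rate <= 1, ins_rate >= 0, ins_rate <= 1,
            del_rate >= 0, del_rate <= 1, chimera_rate >= 0, chimera_rate <= 1)
  structure(list(mean_depth = mean_depth, singlet_inflation = singlet_inflation,
                 sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 base_quality = as.integer(base_quality),
                 error_quality = as.integer(error_quality),
                 chimera_rate = chimera_rate, seed = seed),
            class = "read_sim_config")
}

#' Build a barcoded plasmid library
#'
#' Assigns each of \code{n_clones} clones a unique degenerate barcode
#' (rejection sampling; each barcode used exactly once), a fragment sampled
#' uniformly from the supplied pool, and a uniformly drawn insertion
#' orientation (+ cis / - trans).
#'
#' @param fragments fragment pool as returned by [fragment_template()] (needs
#'   columns start, end, strand).
#' @param n_clones number of clones (>= 1; must not exceed the design
#'   diversity).
#' @param spec a [barcode_spec()].
#' @param reference_id identifier of the reference the fragments live on.
#' @param seed optional integer seed.
#' @return \code{data.frame} of class \code{library_truth}: clone_id, barcode,
#'   start, end, strand.
#' @export
build_library <- function(fragments, n_clones, spec = barcode_spec(),
                          reference_id = "ref", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_clones < 1) stop("n_clones must be >= 1")
  if (nrow(fragments) == 0) stop("fragment pool is empty")
  if (n_clones > design_diversity(spec))
    stop("barcode space exhausted: n_clones exceeds the design diversity")
  idx <- sample.int(nrow(fragments), n_clones, replace = TRUE)
  orientation <- sample(c("+", "-"), n_clones, replace = TRUE)
  strand <- ifelse(orientation == "+", fragments$strand[idx],
                   chartr("+-", "-+", fragments$strand[idx]))
  out <- data.frame(clone_id = seq_len(n_clones),
                    barcode = generate_barcodes(n_clones, spec, unique = TRUE),
                    start = fragments$start[idx], end = fragments$end[idx],
                    strand = strand, stringsAsFactors = FALSE)
  attr(out, "reference_id") <- reference_id
  attr(out, "spec") <- spec
  class(out) <- c("library_truth", "data.frame")
  out
}

#' Inject plasmid-level heterodimers
#'
#' Models the re-ligation failure mode in which a digested plasmid re-closes
#' with the fragment of another plasmid: with probability \code{rate} a
#' clone's fragment assignment is re-paired with another affected clone's
#' fragment before any read is simulated. The re-pairing is a cyclic shift of
#' the affected set, so at \code{rate = 1} (n >= 2) no clone keeps its own
#' fragment.
#'
#' @param truth a [build_library()] table.
#' @param rate probability in \[0, 1\] that a clone is affected.
#' @param seed optional integer seed.
#' @return modified \code{library_truth}.
#' @export
inject_heterodimers <- function(truth, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  aff <- which(runif(nrow(truth)) < rate)
  if (length(aff) >= 2) {
    shift <- sample.int(length(aff) - 1L, 1L)
    perm <- aff[((seq_along(aff) + shift - 1L) %% length(aff)) + 1L]
    truth[aff, c("start", "end", "strand")] <- truth[perm, c("start", "end", "strand")]
  }
  truth
}

mutate_one_base <- function(seq) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(s), 1L)
  s[pos] <- sample(setdiff(c("A", "C", "G", "T"), s[pos]), 1L)
  paste(s, collapse = "")
}

# Apply per-base substitution/indel errors; qualities are emitted alongside
# (correct bases at base_q, error bases at err_q).
mutate_reads <- function(seqs, sub_rate, ins_rate, del_rate,
                         base_q = 37L, err_q = 12L) {
  lens <- nchar(seqs)
  bq <- intToUtf8(base_q + 33L); eq <- intToUtf8(err_q + 33L)
  qual <- vapply(lens, function(l) strrep(bq, l), character(1))
  p <- sub_rate + ins_rate + del_rate
  if (p <= 0) return(list(seq = seqs, qual = qual))
  k <- rbinom(length(seqs), lens, p)
  bases <- c("A", "C", "G", "T")
  for (i in which(k > 0)) {
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    q <- rep(bq, length(s))
    pos <- sort(sample.int(length(s), min(k[i], length(s))))
    type <- sample(c("sub", "ins", "del"), length(pos), replace = TRUE,
                   prob = c(sub_rate, ins_rate, del_rate))
    for (j in rev(seq_along(pos))) {     # right to left keeps positions valid
      pj <- pos[j]
      if (type[j] == "sub") {
        s[pj] <- sample(setdiff(bases, s[pj]), 1L); q[pj] <- eq
      } else if (type[j] == "ins") {
        s <- append(s, sample(bases, 1L), after = pj)
        q <- append(q, eq, after = pj)
      } else {
        s <- s[-pj]; q <- q[-pj]
      }
    }
    seqs[i] <- paste(s, collapse = ""); qual[i] <- paste(q, collapse = "")
  }
  list(seq = seqs, qual = qual)
}

#' Simulate paired reads from a library
#'
#' Per clone the read count is Poisson(\code{mean_depth}); spurious singleton
#' reads are added at rate \code{singlet_inflation} per clone. Read 1 carries
#' flank5 + barcode + flank3, read 2 the fragment in its insertion
#' orientation followed by the fragment-side flank (backbone read-through).
#' With probability \code{chimera_rate} the pair's barcode is replaced by a
#' uniformly chosen other clone's barcode; the truth tag records the switch.
#'
#' @param truth a [build_library()] table (possibly after
#'   [inject_heterodimers()]).
#' @param reference the reference DNA string the fragment coordinates index.
#' @param cfg a [read_sim_config()].
#' @param flanks a [flank_definition()].
#' @return list with \code{reads} (read_id, seq1, qual1, seq2, qual2),
#'   \code{tags} (per-read truth: barcode_clone, fragment_clone, chimeric,
#'   singlet_artifact, true_barcode, start, end, strand) and \code{truth}.
#' @export
simulate_reads <- function(truth, reference, cfg = read_sim_config(),
                           flanks = flank_definition()) {
  if (nrow(truth) == 0) stop("library is empty")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  reference <- toupper(reference)
  n <- nrow(truth)
  depth <- rpois(n, cfg$mean_depth)
  frag_clone <- rep(seq_len(n), depth)

  chim <- runif(length(frag_clone)) < cfg$chimera_rate
  if (any(chim) && n < 2) stop("chimera simulation needs at least 2 clones")
  bc_clone <- frag_clone
  if (any(chim)) {
    r <- sample.int(n - 1L, sum(chim), replace = TRUE)
    bc_clone[chim] <- ifelse(r >= frag_clone[chim], r + 1L, r)
  }
  true_bc <- truth$barcode[bc_clone]
  singlet <- rep(FALSE, length(frag_clone))

  n_sing <- rpois(1L, cfg$singlet_inflation * n)
  if (n_sing > 0) {
    sc <- sample.int(n, n_sing, replace = TRUE)
    frag_clone <- c(frag_clone, sc)
    bc_clone <- c(bc_clone, sc)
    true_bc <- c(true_bc, vapply(truth$barcode[sc], mutate_one_base, character(1)))
    chim <- c(chim, rep(FALSE, n_sing))
    singlet <- c(singlet, rep(TRUE, n_sing))
  }
  if (length(frag_clone) == 0) stop("no reads drawn; increase mean_depth")

  frag_seq <- substring(reference, truth$start[frag_clone] + 1L, truth$end[frag_clone])
  minus <- truth$strand[frag_clone] == "-"
  frag_seq[minus] <- revcomp(frag_seq[minus])

  read1 <- paste0(flanks$flank5, true_bc, flanks$flank3)
  read2 <- paste0(frag_seq, flanks$fragment_flank)
  m1 <- mutate_reads(read1, cfg$sub_rate, cfg$ins_rate, cfg$del_rate,
                     cfg$base_quality, cfg$error_quality)
  m2 <- mutate_reads(read2, cfg$sub_rate, cfg$ins_rate, cfg$del_rate,
                     cfg$base_quality, cfg$error_quality)

  read_id <- sprintf("read_%07d", seq_along(frag_clone))
  reads <- data.frame(read_id = read_id, seq1 = m1$seq, qual1 = m1$qual,
                      seq2 = m2$seq, qual2 = m2$qual, stringsAsFactors = FALSE)
  tags <- data.frame(read_id = read_id,
                     barcode_clone = bc_clone, fragment_clone = frag_clone,
                     chimeric = chim, singlet_artifact = singlet,
                     true_barcode = true_bc,
                     start = truth$start[frag_clone], end = truth$end[frag_clone],
                     strand = truth$strand[frag_clone], stringsAsFactors = FALSE)
  list(reads = reads, tags = tags, truth = truth)
}

#' Write simulated read pairs as FASTQ
#'
#' @param reads the \code{reads} table from [simulate_reads()].
#' @param file1,file2 output FASTQ paths (".gz" suffix compresses).
#' @return invisibly, the two paths.
#' @export
write_paired_fastq <- function(reads, file1, file2) {
  w <- function(seqs, quals, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(x, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = grepl("\\.gz$", path))
  }
  w(reads$seq1, reads$qual1, reads$read_id, file1)
  w(reads$seq2, reads$qual2, reads$read_id, file2)
  invisible(c(file1, file2))
}

#' Read paired FASTQ files into the simulator's read-table layout
#'
#' @param file1,file2 FASTQ paths (optionally gzipped); records are matched
#'   by order and must agree on identifiers.
#' @return \code{data.frame} with read_id, seq1, qual1, seq2, qual2.
#' @export
read_paired_fastq <- function(file1, file2) {
  r1 <- Biostrings::readDNAStringSet(file1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(file2, format = "fastq", with.qualities = TRUE)
  if (length(r1) != length(r2)) stop("mate files differ in record count")
  id1 <- sub("\\s.*$", "", names(r1)); id2 <- sub("\\s.*$", "", names(r2))
  if (!all(id1 == id2)) stop("mate files are not in matching order")
  data.frame(read_id = id1,
             seq1 = as.character(r1), qual1 = as.character(S4Vectors::mcols(r1)$qualities),
             seq2 = as.character(r2), qual2 = as.character(S4Vectors::mcols(r2)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}
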