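# Synthetic quadripartite plastomes and controlled "broken" assembly
# variants. These are the package's test substrate: a circular genome laid
# out LSC-IRa-SSC-IRb whose planted inverted repeat is, by construction,
# the unique maximal one, plus variant operations reproducing the failure
# modes real assemblers show (rotation, strand flips, SSC flips,
# fragmentation, unresolved duplications, missing regions).

#' Generate a synthetic quadripartite plastome
#'
#' Builds a circular sequence `LSC + IRa + SSC + IRb` where `IRb` is the
#' exact reverse complement of `IRa`. Single-copy regions are uniform
#' random DNA, rejection-sampled so that no incidental inverted repeat of
#' 32 bp or more exists anywhere outside the planted pair, and the bases
#' flanking the IRs are adjusted so the planted repeat cannot be extended:
#' the planted structure is the unique answer IR detection should find.
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bp; `lsc_len` must
#'   exceed `ssc_len`. Defaults give a 135 kb plastome typical of
#'   land-plant chloroplast genomes (120-160 kbp, IRs of 10-76 kbp).
#' @param seed Integer seed; output is deterministic per seed.
#' @param id Sequence id of the genome.
#' @return A list with `genome` (one-row circular sequence table) and
#'   `structure` (a [quadripartite] region map).
#' @examples
#' p <- make_plastome(lsc_len = 2000, ssc_len = 500, ir_len = 400, seed = 1)
#' nchar(p$genome$seq)  # 2000 + 500 + 2 * 400
#' @export
make_plastome <- function(lsc_len = 80000, ssc_len = 15000, ir_len = 20000,
                          seed = 1, id = "plastome") {
  if (!(lsc_len > ssc_len && ssc_len >= 1 && ir_len >= 1)) {
    abort("Require lsc_len > ssc_len >= 1 and ir_len >= 1.")
  }
  set.seed(seed)
  for (attempt in 1:25) {
    lsc <- block_junctions(random_dna(lsc_len))
    ssc <- block_junctions(random_dna(ssc_len))
    ira <- random_dna(ir_len)
    genome <- paste0(lsc, ira, ssc, revcomp(ira))
    if (ir_screen_clean(genome, lsc_len, ssc_len, ir_len)) {
      structure <- new_quadripartite(
        lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len
      )
      return(list(
        genome = seq_record(id, genome, topology = "circular"),
        structure = structure
      ))
    }
  }
  abort("Failed to sample an incidental-repeat-free plastome.") # nocov
}

# Make the first base of a single-copy block non-complementary to its last
# base, so a planted IR pair flanking the block cannot extend across it.
#' @keywords internal
block_junctions <- function(block) {
  n <- nchar(block)
  last <- substr(block, n, n)
  if (substr(block, 1, 1) == complement_base(last)) {
    allowed <- setdiff(c("A", "C", "G", "T"), complement_base(last))
    substr(block, 1, 1) <- sample(allowed, 1)
  }
  block
}

# TRUE when every k-mer whose reverse complement occurs elsewhere in the
# circular genome lies inside the planted IR copies. Catches incidental
# inverted repeats >= 32 bp (any repeat that long shares a 32-mer).
#' @keywords internal
ir_screen_clean <- function(genome, lsc_len, ssc_len, ir_len, k = 32L) {
  n <- nchar(genome)
  if (n < k) {
    return(TRUE)
  }
  fwd <- kmer_vector(paste0(genome, genome), k)
  rcv <- kmer_vector(paste0(revcomp(genome), revcomp(genome)), k)
  pos <- (which(fwd %in% unique(rcv)) - 1L) %% n
  if (ir_len >= k) {
    ira_ok <- pos >= lsc_len & pos <= lsc_len + ir_len - k
    irb_ok <- pos >= lsc_len + ir_len + ssc_len & pos <= n - k
    pos <- pos[!(ira_ok | irb_ok)]
  }
  length(pos) == 0
}

#' Generate a random linear sequence component
#'
#' Uniform random DNA, used as a stand-in for nuclear or mitochondrial
#' background sequence in read-mixture simulations.
#'
#' @param length Sequence length in bp (>= 1).
#' @param seed Integer seed.
#' @param id Sequence id.
#' @param topology `"linear"` (default) or `"circular"`.
#' @return A one-row sequence table.
#' @export
make_component <- function(length, seed = 1, id = "component",
                           topology = "linear") {
  if (length < 1) abort("`length` must be >= 1.")
  set.seed(seed)
  seq_record(id, random_dna(length), topology = topology)
}

#' Derive a controlled assembly variant from a genome
#'
#' Produces the structural failure modes seen in real chloroplast
#' assemblies: start-point rotation, global reverse complement, a flipped
#' SSC (both biologically valid presentations of the same circular
#' molecule), fragmentation into contigs, an unresolved tandem
#' duplication, and a missing region.
#'
#' @param genome One-row circular sequence table in canonical
#'   LSC-first layout (as produced by [make_plastome()]).
#' @param variant One of `"rotate"`, `"revcomp"`, `"flip_ssc"`,
#'   `"split"`, `"tandem_duplicate"`, `"drop_region"`.
#' @param structure [quadripartite] region map; required for
#'   `"flip_ssc"`.
#' @param offset Rotation offset in bp (for `"rotate"`).
#' @param n_pieces Number of contigs (for `"split"`).
#' @param positions Optional 0-based cut positions (for `"split"`);
#'   evenly spaced when omitted.
#' @param start,end 0-based half-open interval to delete (for
#'   `"drop_region"`).
#' @return A sequence table with one row per contig.
#' @export
make_variant <- function(genome, variant, structure = NULL, offset = 0,
                         n_pieces = 2, positions = NULL, start = NULL,
                         end = NULL) {
  genome <- validate_seq_tbl(genome)
  stopifnot(nrow(genome) == 1)
  s <- genome$seq
  n <- nchar(s)
  id <- genome$id
  switch(match.arg(variant, c(
    "rotate", "revcomp", "flip_ssc", "split", "tandem_duplicate",
    "drop_region"
  )),
  rotate = {
    if (genome$topology != "circular") abort("rotate needs a circular sequence.")
    if (offset < 0 || offset >= n) abort("rotation offset out of range.")
    seq_record(paste0(id, "_rot", offset), circ_substr(s, offset, n),
      topology = "circular"
    )
  },
  revcomp = seq_record(paste0(id, "_rc"), revcomp(s), topology = genome$topology),
  flip_ssc = {
    if (is.null(structure)) abort("flip_ssc needs a structure.")
    ssc <- structure$regions[structure$regions$region == "ssc", ]
    if (ssc$end > n) abort("SSC interval wraps; use the canonical layout.")
    flipped <- paste0(
      substr(s, 1, ssc$start),
      revcomp(substr(s, ssc$start + 1, ssc$end)),
      substr(s, ssc$end + 1, n)
    )
    seq_record(paste0(id, "_sscflip"), flipped, topology = "circular")
  },
  split = {
    if (is.null(positions)) {
      if (n_pieces < 1) abort("n_pieces must be >= 1.")
      positions <- floor(seq_len(n_pieces - 1) * n / n_pieces)
    }
    positions <- sort(unique(as.integer(positions)))
    if (length(positions) > 0 && (min(positions) < 1 || max(positions) > n - 1)) {
      abort("cut positions out of range.")
    }
    bounds <- c(0, positions, n)
    seq_record(
      paste0(id, "_part", seq_len(length(bounds) - 1)),
      substring(s, bounds[-length(bounds)] + 1, bounds[-1]),
      topology = "linear"
    )
  },
  tandem_duplicate = seq_record(paste0(id, "_tandem"), paste0(s, s),
    topology = "circular"
  ),
  drop_region = {
    if (is.null(start) || is.null(end) || start < 0 || end > n || start >= end) {
      abort("drop_region needs 0 <= start < end <= length.")
    }
    if (end - start >= n) abort("cannot drop the whole sequence.")
    seq_record(
      paste0(id, "_drop", start, "_", end),
      paste0(substr(s, 1, start), substr(s, end + 1, n)),
      topology = "linear"
    )
  }
  )
}
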