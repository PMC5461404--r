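#' Count Pro-Pro duets and Pro-Pro-Pro triplets in a protein sequence
#'
#' Occurrences are counted with overlap ("PPPP" holds 3 duets and 2
#' triplets); set `overlapping = FALSE` for disjoint counting.
#'
#' @param sequence amino-acid string over the 20-letter alphabet.
#' @param overlapping count overlapping occurrences (default TRUE).
#' @return named integer vector c(duets, triplets).
#' @examples
#' countProPro("MPPAPPG")  # 2 duets, 0 triplets
#' @export
countProPro <- function(sequence, overlapping = TRUE) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  valid <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V")
  bad <- which(!aa %in% valid)
  if (length(bad))
    stop("countProPro: invalid letter '", aa[bad[1]], "' at position ",
         bad[1])
  isP <- aa == "P"
  n <- length(aa)
  if (n < 2) return(c(duets = 0L, triplets = 0L))
  duetPos <- isP[-n] & isP[-1]
  tripPos <- if (n >= 3) isP[seq_len(n - 2)] & isP[seq_len(n - 2) + 1L] &
                         isP[seq_len(n - 2) + 2L] else logical(0)
  if (overlapping) {
    c(duets = sum(duetPos), triplets = sum(tripPos))
  } else {
    countDisjoint <- function(hits, w) {
      cnt <- 0L; i <- 1L
      while (i <= length(hits)) {
        if (hits[i]) { cnt <- cnt + 1L; i <- i + w } else i <- i + 1L
      }
      cnt
    }
    c(duets = countDisjoint(duetPos, 2L),
      triplets = countDisjoint(tripPos, 3L))
  }
}

#' Copy-weighted Pro-Pro motif fraction of a proteome sample
#'
#' Sum over records of (Pro-Pro count x copies) divided by the sum of
#' (length x copies): the fraction of translated codon positions that
#' begin a Pro-Pro motif. Invariant under uniform copy-number scaling.
#'
#' @param records data.frame with columns `length`, `copies_per_cell`,
#'   and either `pro_pro_count` or `sequence` (counted on the fly).
#' @return the motif fraction (dimensionless).
#' @export
motifFraction <- function(records) {
  stopifnot(nrow(records) > 0)
  if (is.null(records$pro_pro_count)) {
    if (is.null(records$sequence))
      stop("motifFraction: need pro_pro_count or sequence")
    records$pro_pro_count <- vapply(records$sequence,
                                    function(s) countProPro(s)[["duets"]],
                                    integer(1))
    if (is.null(records$length))
      records$length <- nchar(records$sequence)
  }
  num <- sum(records$pro_pro_count * records$copies_per_cell)
  den <- sum(records$length * records$copies_per_cell)
  if (den <= 0) stop("motifFraction: copy-weighted total length is zero")
  num / den
}

#' Pro-Pro motifs in the single-cell transcriptome
#'
#' motifs/cell = mRNA copies x codons per mRNA x motif fraction.
#'
#' @param fraction Pro-Pro motif fraction.
#' @param mrnaCopies mRNA copies per cell.
#' @param codonsPerMrna mean codons per mRNA.
#' @return list with `value` (unrounded) and `rounded` (2 significant
#'   figures).
#' @export
motifsPerCell <- function(fraction, mrnaCopies, codonsPerMrna) {
  stopifnot(fraction >= 0, mrnaCopies > 0, codonsPerMrna > 0)
  v <- fraction * mrnaCopies * codonsPerMrna
  list(value = v, rounded = round2sf(v))
}

#' Molar concentration of copies in a cell volume
#'
#' @param copies copy number.
#' @param volume cell volume, um^3 (1 um^3 = 1e-15 L).
#' @return concentration, mol/L.
#' @export
molarity <- function(copies, volume) {
  stopifnot(copies >= 0, volume > 0)
  copies / (volume * 1e-15 * 6.02214076e23)
}

#' Effective bimolecular binding rate constant
#'
#' k_bimol = (1/tau_free) / [target], with the search time in ms. Also
#' reports the ratio of the diffusion-limited rate to k_bimol.
#'
#' @param tauFree mean search time, ms.
#' @param concentration target concentration, mol/L.
#' @param kDiff diffusion-limited rate constant, M^-1 s^-1 (literature
#'   constant, default 4e8).
#' @return list: `kBimol` (M^-1 s^-1), `ratioToDiffusionLimit`.
#' @export
bimolecularRate <- function(tauFree, concentration, kDiff = 4e8) {
  stopifnot(tauFree > 0, concentration > 0)
  k <- (1000 / tauFree) / concentration
  list(kBimol = k, ratioToDiffusionLimit = kDiff / k)
}

#' Census parameters
#'
#' Printed-input constants for the interrogation-budget arithmetic, with
#' the defaults of rapidly growing E. coli: ~2,000 mRNA/cell, 260
#' codons/mRNA, 50,000 total 30S of which 80% translate, 3 um^3 volume,
#' 20 aa/s elongation, 5,000-20,000 EF-P copies, 30% bound, lifetimes
#' 16/7 ms.
#'
#' @param mrnaCopiesPerCell,codonsPerMrna,total30S,translatingFraction
#'   transcriptome/ribosome constants.
#' @param cellVolume um^3.
#' @param translationRate aa/s.
#' @param efpCopiesLow,efpCopiesHigh copy-number bracket.
#' @param fSlow bound fraction.
#' @param tauFree,tauBound ms.
#' @param kDiff diffusion-limited rate constant, M^-1 s^-1.
#' @return validated list of class "CensusParams".
#' @export
censusParams <- function(mrnaCopiesPerCell = 2000, codonsPerMrna = 260,
                         total30S = 50000, translatingFraction = 0.8,
                         cellVolume = 3, translationRate = 20,
                         efpCopiesLow = 5000, efpCopiesHigh = 20000,
                         fSlow = 0.30, tauFree = 16, tauBound = 7,
                         kDiff = 4e8) {
  p <- list(mrnaCopiesPerCell = mrnaCopiesPerCell,
            codonsPerMrna = codonsPerMrna, total30S = total30S,
            translatingFraction = translatingFraction,
            cellVolume = cellVolume, translationRate = translationRate,
            efpCopiesLow = efpCopiesLow, efpCopiesHigh = efpCopiesHigh,
            fSlow = fSlow, tauFree = tauFree, tauBound = tauBound,
            kDiff = kDiff)
  stopifnot(all(vapply(p, function(x) is.numeric(x) && x > 0, logical(1))),
            translatingFraction <= 1, efpCopiesLow <= efpCopiesHigh)
  structure(p, class = "CensusParams")
}

#' The E-site interrogation budget
#'
#' Chains the census arithmetic: binding/unbinding cycle time
#' tau_free + tau_bound; cycles per copy per second; total E-site
#' interrogations per second for the copy-number bracket; translating
#' ribosomes and the per-ribosome visit rate; total elongation cycles
#' per second and the upper limit on a single elongation cycle; and the
#' snapshot count of simultaneously bound complexes f_slow x copies.
#' All headline numbers are reported unrounded with a 2-significant-
#' figure companion in `rounded`.
#'
#' @param params a [censusParams()] list.
#' @return list of class "CensusReport".
#' @export
interrogationBudget <- function(params) {
  stopifnot(inherits(params, "CensusParams"))
  cycleTime <- params$tauFree + params$tauBound            # ms
  cyclesPerCopy <- 1000 / cycleTime                        # 1/s
  interLow <- params$efpCopiesLow * cyclesPerCopy
  interHigh <- params$efpCopiesHigh * cyclesPerCopy
  translating <- params$total30S * params$translatingFraction
  conc <- molarity(translating, params$cellVolume)
  kb <- bimolecularRate(params$tauFree, conc, params$kDiff)
  rep <- list(
    cycleTime = cycleTime,
    cyclesPerCopyPerS = cyclesPerCopy,
    interrogationsPerS = c(low = interLow, high = interHigh),
    translatingRibosomes = translating,
    ribosomeConcentration = conc,
    kBimol = kb$kBimol,
    kDiffRatio = kb$ratioToDiffusionLimit,
    perRibosomeVisitsPerS = c(low = interLow / translating,
                              high = interHigh / translating),
    elongationCyclesPerS = translating * params$translationRate,
    elongationCycleUpperMs = 1000 / params$translationRate,
    snapshotComplexes = c(low = params$fSlow * params$efpCopiesLow,
                          high = params$fSlow * params$efpCopiesHigh))
  rep$rounded <- lapply(rep, round2sf)
  structure(rep, class = "CensusReport")
}

#' Generate a synthetic proteome table
#'
#' Random protein records whose copy-weighted Pro-Pro motif fraction is
#' tuned to a target (a stand-in for a measured single-cell proteome
#' abundance table; entirely synthetic). Base sequences are drawn from
#' the 19 non-proline letters; "PP" duets are then inserted at spaced
#' positions, genes chosen with probability proportional to
#' length x copies, until the copy-weighted motif count reaches the
#' target. Deterministic given the seed.
#'
#' @param nGenes number of genes.
#' @param meanLength mean protein length, codons (exponentialish spread).
#' @param targetMotifFraction desired copy-weighted motif fraction.
#' @param copyDist function(n) returning copy numbers (default lognormal
#'   around ~3,000 copies).
#' @param seed integer seed.
#' @return data.frame: gene_id, length, sequence, pro_pro_count,
#'   copies_per_cell.
#' @export
syntheticProteome <- function(nGenes, meanLength = 260,
                              targetMotifFraction = 5.3e-4,
                              copyDist = NULL, seed = 1L) {
  if (is.null(copyDist))
    copyDist <- function(n) pmax(20, round(stats::rlnorm(n, log(1000), 1.2)))
  withSeed(seed, {
    lens <- pmax(30L, stats::rpois(nGenes, meanLength))
    copies <- copyDist(nGenes)
    maxFraction <- 0.25  # spaced insertion cannot exceed ~1 duet / 4 codons
    if (targetMotifFraction >= maxFraction)
      stop("syntheticProteome: infeasible target fraction")
    letters19 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                   "K", "M", "F", "S", "T", "W", "Y", "V")
    seqs <- vapply(lens, function(L)
      paste(sample(letters19, L, replace = TRUE), collapse = ""),
      character(1))
    motifs <- integer(nGenes)
    if (targetMotifFraction > 0) {
      W <- sum(as.numeric(lens) * copies)
      targetCount <- targetMotifFraction * W
      capacity <- lens %/% 4L   # spaced, non-overlapping duets
      acc <- 0
      prob <- as.numeric(lens) * copies
      while (acc < targetCount && any(prob > 0)) {
        g <- sample.int(nGenes, 1L, prob = prob)
        if (motifs[g] >= capacity[g]) { prob[g] <- 0; next }
        # skip genes whose copy weight would overshoot past the target
        if (acc + copies[g] - targetCount > targetCount - acc) {
          prob[g] <- 0; next
        }
        motifs[g] <- motifs[g] + 1L
        acc <- acc + copies[g]
      }
      if (abs(acc - targetCount) > 0.1 * targetCount)
        stop("syntheticProteome: infeasible target fraction for this table")
      for (g in which(motifs > 0)) {
        s <- strsplit(seqs[g], "")[[1]]
        pos <- seq(2L, by = 4L, length.out = motifs[g])
        for (p in pos) { s[p] <- "P"; s[p + 1L] <- "P" }
        seqs[g] <- paste(s, collapse = "")
      }
    }
    data.frame(gene_id = sprintf("gene%04d", seq_len(nGenes)),
               length = lens, sequence = seqs, pro_pro_count = motifs,
               copies_per_cell = copies)
  })
}
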