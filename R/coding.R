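# Synonymous/nonsynonymous site accounting (Nei-Gojobori 1986) and
# single-variant consequence calls on an in-frame CDS.

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

split_codons <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length must be divisible by 3")
  if (nchar(cds) == 0L) return(character(0))
  substring(cds, seq(1L, nchar(cds), by = 3L), seq(3L, nchar(cds), by = 3L))
}

#' Count synonymous and nonsynonymous sites in a CDS
#'
#' Nei-Gojobori fractional site counts: at each codon position the
#' synonymous fraction is the number of the three possible single-base
#' changes that preserve the amino acid, divided by 3, summed over all
#' positions of all codons. Changes that create a stop codon are excluded
#' from the synonymous tally but the per-position denominator stays 3, so
#' totals satisfy `syn + nonsyn = 3 * codons` (stop-creating paths in effect
#' count as nonsynonymous).
#'
#' @param cds in-frame coding sequence (length divisible by 3, no internal
#'   stop codons).
#' @return list with `syn_sites` and `nonsyn_sites` (fractional counts).
#' @export
#' @examples
#' count_syn_nonsyn_sites("GGG")  # syn 1, nonsyn 2
count_syn_nonsyn_sites <- function(cds) {
  codons <- split_codons(cds)
  if (length(codons) == 0L) return(list(syn_sites = 0, nonsyn_sites = 0))
  aas <- codon_aa(codons)
  if (any(aas[-length(aas)] == "*"))
    stop("internal stop codon in reference frame")
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (codon in codons) {
    ref_aa <- codon_aa(codon)
    for (p in 1:3) {
      for (b in setdiff(bases, substr(codon, p, p))) {
        mut <- codon
        substr(mut, p, p) <- b
        mut_aa <- codon_aa(mut)
        if (mut_aa != "*" && mut_aa == ref_aa) syn <- syn + 1 / 3
      }
    }
  }
  list(syn_sites = syn, nonsyn_sites = 3 * length(codons) - syn)
}

#' Classify a single-nucleotide variant in a CDS
#'
#' Translates the affected codon before and after the change. A change in
#' the first codon that destroys the ATG is a start-loss; a change creating
#' a stop codon is nonsense; otherwise synonymous or nonsynonymous by amino
#' acid identity.
#'
#' @param cds in-frame coding sequence.
#' @param position 1-based position of the variant within the CDS.
#' @param alt alternative base, different from the reference base.
#' @return one of `"synonymous"`, `"nonsynonymous"`, `"start-loss"`,
#'   `"nonsense"`.
#' @export
#' @examples
#' classify_snv("ATGGGG", 2, "C")  # start-loss (ATG > ACG)
classify_snv <- function(cds, position, alt) {
  cds <- toupper(cds)
  alt <- toupper(alt)
  if (position < 1L || position > nchar(cds)) stop("position outside CDS")
  if (!alt %in% c("A", "C", "G", "T")) stop("alt must be one of A, C, G, T")
  ref <- substr(cds, position, position)
  if (alt == ref) stop("alt equals the reference base at position ", position)
  codon_idx <- (position - 1L) %/% 3L + 1L
  within <- (position - 1L) %% 3L + 1L
  codon <- split_codons(cds)[codon_idx]
  mut <- codon
  substr(mut, within, within) <- alt
  if (codon_idx == 1L && codon == "ATG" && mut != "ATG") return("start-loss")
  mut_aa <- codon_aa(mut)
  if (mut_aa == "*") return("nonsense")
  if (mut_aa == codon_aa(codon)) "synonymous" else "nonsynonymous"
}
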