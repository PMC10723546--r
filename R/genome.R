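#' Human autosome lengths and centromere positions (GRCh38, approximate)
#'
#' Chromosome lengths and centromere midpoints rounded to 0.1 Mb, sufficient
#' for arm-level bookkeeping (arm alteration matrices, wGII denominators).
#' Acrocentric short arms (13p, 14p, 15p, 21p, 22p) carry almost no unique
#' sequence; [human_arms()] drops them by default, leaving 39 usable arms.
#'
#' @return data.frame with columns `chrom`, `length`, `centromere` (bp).
#' @export
human_autosomes <- function() {
  data.frame(
    chrom = paste0("chr", 1:22),
    length = c(248956422, 242193529, 198295559, 190214555, 181538259,
               170805979, 159345973, 145138636, 138394717, 133797422,
               135086622, 133275309, 114364328, 107043718, 101991189,
               90338345, 83257441, 80373285, 58617616, 64444167,
               46709983, 50818468),
    centromere = c(123400000, 93900000, 90900000, 50000000, 48800000,
                   59800000, 60100000, 45200000, 43000000, 39800000,
                   53400000, 35500000, 17700000, 17200000, 19000000,
                   36800000, 25100000, 18500000, 26200000, 28100000,
                   12000000, 15000000),
    stringsAsFactors = FALSE
  )
}

#' Arm definitions derived from a genome table
#'
#' @param genome data.frame with `chrom`, `length` and either `centromere` or
#'   `arm_boundary` columns (bp).
#' @param drop_acrocentric drop the gene-poor short arms of chr13/14/15/21/22
#'   (only meaningful for the human genome).
#' @return data.frame with columns `chrom`, `arm` ("p"/"q"), `start`, `end`
#'   (1-based inclusive).
#' @export
arm_definitions <- function(genome, drop_acrocentric = TRUE) {
  boundary <- genome$centromere %||% genome$arm_boundary
  stopifnot(all(boundary > 0), all(boundary < genome$length))
  arms <- rbind(
    data.frame(chrom = genome$chrom, arm = "p", start = 1L, end = boundary),
    data.frame(chrom = genome$chrom, arm = "q", start = boundary + 1L,
               end = genome$length)
  )
  if (drop_acrocentric) {
    acro <- paste0("chr", c(13, 14, 15, 21, 22))
    arms <- arms[!(arms$chrom %in% acro & arms$arm == "p"), ]
  }
  arms <- arms[order(match(arms$chrom, genome$chrom), arms$arm), ]
  rownames(arms) <- NULL
  arms
}

#' Human chromosome-arm table
#' @inheritParams arm_definitions
#' @export
human_arms <- function(drop_acrocentric = TRUE) {
  arm_definitions(human_autosomes(), drop_acrocentric = drop_acrocentric)
}

#' A small synthetic genome for simulation and tests
#'
#' Scaled-down genome keeping the structural features the pipeline relies on
#' (multiple chromosomes, an arm boundary inside each) while staying cheap to
#' simulate at realistic per-Mb mutation rates.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param arm_fraction position of the arm boundary as a fraction of length.
#' @return data.frame with `chrom`, `length`, `arm_boundary`.
#' @export
synthetic_genome <- function(n_chrom = 4, chrom_length = 6e7,
                             arm_fraction = 0.45) {
  stopifnot(n_chrom >= 1, chrom_length > 0,
            arm_fraction > 0, arm_fraction < 1)
  data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    length = rep(as.integer(chrom_length), n_chrom),
    arm_boundary = rep(as.integer(round(chrom_length * arm_fraction)), n_chrom),
    stringsAsFactors = FALSE
  )
}
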