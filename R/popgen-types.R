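# Containers for mtDNA haplotype samples and diploid microsatellite tables.

#' Haplotype sample for one site
#'
#' Equal-length aligned nucleotide sequences (alphabet A, C, G, T, N, -) for
#' the individuals sampled at one site. `N`, gaps and any other ambiguity
#' code are treated as missing at that position (pairwise deletion in all
#' distance computations); haplotype identity is exact string equality.
#'
#' @param sequences character vector of aligned sequences.
#' @param site site code.
#' @param lineage lineage label(s), recycled to one per individual.
#' @return a `haplotype_set`.
#' @export
haplotype_set <- function(sequences, site = "S1", lineage = NA_character_) {
  sequences <- toupper(as.character(sequences))
  if (length(unique(nchar(sequences))) > 1) {
    fail("all sequences must have the same length")
  }
  if (any(!grepl("^[ACGTNRYSWKMBDHV-]*$", sequences))) {
    fail("sequences may only contain nucleotide/ambiguity codes and '-'")
  }
  structure(list(site = site, sequences = sequences,
                 lineage = rep_len(lineage, length(sequences))),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("Haplotype set '%s': %d sequences of length %d, %d haplotypes\n",
              x$site, length(x$sequences), nchar(x$sequences[1] %||% ""),
              length(unique(x$sequences))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# integer matrix (n x L) with A,C,G,T -> 1..4 and everything else NA
seq_to_int <- function(sequences) {
  if (!length(sequences)) return(matrix(integer(0), 0, 0))
  chars <- strsplit(sequences, "", fixed = TRUE)
  m <- matrix(unlist(chars), nrow = length(sequences), byrow = TRUE)
  out <- matrix(NA_integer_, nrow(m), ncol(m))
  out[m == "A"] <- 1L
  out[m == "C"] <- 2L
  out[m == "G"] <- 3L
  out[m == "T"] <- 4L
  out
}

# Pairwise sequence comparison with pairwise deletion. Returns, for the
# unique haplotypes of `sequences`, matrices of differing-site counts and
# comparable-site counts, plus the haplotype index of each individual.
hap_distances <- function(sequences) {
  uniq <- unique(sequences)
  id <- match(sequences, uniq)
  k <- length(uniq)
  M <- seq_to_int(uniq)
  diffs <- matrix(0, k, k)
  sites <- matrix(ncol(M), k, k)
  if (k > 1) {
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        ok <- !is.na(M[a, ]) & !is.na(M[b, ])
        diffs[a, b] <- diffs[b, a] <- sum(M[a, ok] != M[b, ok])
        sites[a, b] <- sites[b, a] <- sum(ok)
      }
    }
  }
  list(diffs = diffs, sites = sites, id = id, k = k)
}

#' Diploid microsatellite genotype table
#'
#' Stores two allele calls (repeat-length integers, `NA` = missing) per locus
#' per individual, with a site code per individual and the repeat unit length
#' of each locus (needed for Bruvo distances).
#'
#' @param alleles integer array of dimension (individuals, loci, 2).
#' @param site site code per individual.
#' @param loci locus names (default from the array dimnames or `L1..`).
#' @param repeat_units repeat unit length (>= 1) per locus.
#' @return a `genotype_table`.
#' @export
genotype_table <- function(alleles, site, loci = NULL, repeat_units = NULL) {
  alleles <- as.array(alleles)
  if (length(dim(alleles)) != 3 || dim(alleles)[3] != 2) {
    fail("alleles must be an (individuals x loci x 2) array")
  }
  storage.mode(alleles) <- "integer"
  n <- dim(alleles)[1]
  nl <- dim(alleles)[2]
  if (length(site) != n) fail("one site code per individual required")
  if (is.null(loci)) loci <- dimnames(alleles)[[2]] %||% paste0("L", seq_len(nl))
  if (is.null(repeat_units)) repeat_units <- rep(1L, nl)
  if (length(repeat_units) != nl) fail("one repeat unit per locus required")
  if (any(repeat_units < 1)) fail("repeat units must be >= 1")
  structure(list(alleles = alleles, site = as.character(site),
                 loci = as.character(loci),
                 repeat_units = as.numeric(repeat_units)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d individuals, %d loci, %d sites\n",
              dim(x$alleles)[1], dim(x$alleles)[2],
              length(unique(x$site))))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$alleles))))
  invisible(x)
}

# subset a genotype table to the individuals in `idx`
gt_subset <- function(gt, idx) {
  genotype_table(gt$alleles[idx, , , drop = FALSE], gt$site[idx],
                 gt$loci, gt$repeat_units)
}
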