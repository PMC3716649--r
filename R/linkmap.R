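# Two-point linkage placement of a biallelic marker on a doubled-haploid
# (DH) map.  DH lines are fully homozygous, so the recombination fraction
# between two markers is estimated by direct counting of recombinant lines
# among lines scored at both markers.

#' Kosambi map function (recombination fraction -> cM)
#' @param r recombination fraction in [0, 0.5).
#' @export
kosambi <- function(r) 25 * log((1 + 2 * r) / (1 - 2 * r))

#' Haldane map function (recombination fraction -> cM)
#' @param r recombination fraction in [0, 0.5).
#' @export
haldane <- function(r) -50 * log(1 - 2 * r)

#' Two-point linkage between two markers in a DH population
#'
#' @param m1,m2 genotype vectors over the same lines, coded "A"/"B" with NA
#'   (or "-") for missing; missing genotypes are excluded pairwise.
#' @param map_function "kosambi" or "haldane".
#' @return list of class `linkage_result`: n_informative, n_recombinant, r,
#'   cM, lod, p (one-sided binomial test of r < 0.5), phase ("coupling" or
#'   "repulsion"; r is estimated after phase correction and never exceeds
#'   0.5).
#' @export
two_point <- function(m1, m2, map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  m1 <- toupper(as.character(m1)); m2 <- toupper(as.character(m2))
  m1[m1 %in% c("-", "")] <- NA; m2[m2 %in% c("-", "")] <- NA
  ok <- !is.na(m1) & !is.na(m2)
  n <- sum(ok)
  if (n < 2L) stop("fewer than 2 informative lines")
  rec <- sum(m1[ok] != m2[ok])
  phase <- "coupling"
  if (rec > n - rec) {           # repulsion: alleles coded in opposite phase
    rec <- n - rec
    phase <- "repulsion"
  }
  r <- rec / n
  lod <- if (r == 0) n * log10(2) else
    rec * log10(r / 0.5) + (n - rec) * log10((1 - r) / 0.5)
  p <- stats::pbinom(rec, n, 0.5)
  d <- switch(map_function, kosambi = kosambi(r), haldane = haldane(r))
  structure(list(n_informative = n, n_recombinant = rec, r = r, cM = d,
                 lod = lod, p = p, phase = phase, map_function = map_function),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("<linkage_result> r = %.4f (%d/%d), %.2f cM (%s), LOD %.2f, p = %.3g, %s\n",
              x$r, x$n_recombinant, x$n_informative, x$cM, x$map_function,
              x$lod, x$p, x$phase))
  invisible(x)
}

#' Place a new marker on an existing map by two-point linkage
#'
#' Tests the new marker against every map marker; significant linkages
#' (binomial p < alpha) are ranked by recombination fraction and the best
#' placement returned.
#'
#' @param new_marker genotype vector for the marker to place.
#' @param map data.frame with columns marker, chromosome, cM.
#' @param genotypes data.frame/matrix of genotypes, lines x markers, with
#'   columns matching `map$marker`.
#' @param alpha significance threshold (default 0.001, high stringency).
#' @param map_function passed to [two_point()].
#' @return list: placed (logical), marker, chromosome, position_cM (map
#'   position of the linked marker), distance_cM, r, lod, p, and `tests`
#'   (per-marker table).
#' @export
place_marker <- function(new_marker, map, genotypes, alpha = 0.001,
                         map_function = "kosambi") {
  stopifnot(all(map$marker %in% colnames(genotypes)))
  tests <- lapply(map$marker, function(mk) {
    res <- tryCatch(two_point(new_marker, genotypes[, mk], map_function),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(marker = mk, chromosome = map$chromosome[map$marker == mk],
               position_cM = map$cM[map$marker == mk], r = res$r,
               distance_cM = res$cM, lod = res$lod, p = res$p,
               n_informative = res$n_informative, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, tests[!vapply(tests, is.null, TRUE)])
  sig <- tests[tests$p < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(list(placed = FALSE, tests = tests))
  }
  best <- sig[order(sig$r, sig$p), , drop = FALSE][1L, ]
  list(placed = TRUE, marker = best$marker, chromosome = best$chromosome,
       position_cM = best$position_cM, distance_cM = best$distance_cM,
       r = best$r, lod = best$lod, p = best$p, tests = tests)
}

#' Simulate DH genotypes for a marker linked at a given r
#'
#' Utility for power studies and tests: draws a marker whose recombination
#' fraction with `parent` is `r` in a DH population.
#'
#' @param parent genotype vector ("A"/"B").
#' @param r true recombination fraction.
#' @return genotype vector.
#' @export
sim_linked_marker <- function(parent, r) {
  flip <- stats::runif(length(parent)) < r
  ifelse(flip, ifelse(parent == "A", "B", "A"), parent)
}
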