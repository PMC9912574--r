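#' Run a pedigree or single-step genomic evaluation
#'
#' Assembles the relationship inverse (`A^-1`, or `H^-1` when genotypes are
#' supplied), builds and solves the mixed model equations at fixed variance
#' components, and returns solutions plus the genomic by-products needed for
#' backsolving SNP effects.
#'
#' @param data records data.frame (see [mme_structure()]).
#' @param ped a [renumber_pedigree()] pedigree.
#' @param vc a [vc_components()].
#' @param spec a [model_spec()]; defaults to the two-trait FY/BW model.
#' @param geno optional [geno_matrix()] of genotyped animals (ssGBLUP).
#' @param weights optional SNP weights (default 1).
#' @param tau blending weight of G towards A22 (default 0.05; 0 = none).
#' @param base_freq optional base allele frequencies; estimated by
#'   [estimate_base_frequencies()] when missing.
#' @return object of class `gs_fit` : the [solve_mme()] solutions plus
#'   `mode`, and for ssGBLUP the matrices `G`, `G_inv`, `A22_inv`, `Z`,
#'   `lambda`, `p`, `d` and the genotyped index.
#' @export
genetic_evaluation <- function(data, ped, vc, spec = trout_model_spec(),
                               geno = NULL, weights = NULL, tau = 0.05,
                               base_freq = NULL) {
  A_inv <- build_A_inverse(ped)
  if (is.null(geno)) {
    fit <- solve_mme(build_mme(mme_structure(spec, data, A_inv), vc))
    fit$mode <- "pblup"
    class(fit) <- c("gs_fit", class(fit))
    return(fit)
  }
  gidx <- match(geno$ids, ped$labels)
  if (anyNA(gidx))
    stop("genotyped animals absent from pedigree: ",
         paste(geno$ids[is.na(gidx)], collapse = ", "))
  a22 <- build_A22(ped, geno$ids)
  if (is.null(base_freq))
    base_freq <- estimate_base_frequencies(geno, a22$A22_inv, a22$A22)
  if (is.null(weights)) weights <- rep(1, length(base_freq))
  gb <- build_G(geno, base_freq, weights)
  G <- blend_G(gb$G, a22$A22, tau)
  G_inv <- chol2inv(chol(G))
  dimnames(G_inv) <- dimnames(G)
  H_inv <- build_H_inverse(A_inv, G_inv, a22$A22_inv, gidx)
  fit <- solve_mme(build_mme(mme_structure(spec, data, H_inv), vc))
  fit$mode <- "ssgblup"
  fit$G <- G; fit$G_inv <- G_inv; fit$A22_inv <- a22$A22_inv
  fit$Z <- gb$Z; fit$lambda <- gb$lambda
  fit$p <- base_freq; fit$d <- weights
  fit$genotyped <- geno$ids; fit$genotyped_index <- gidx
  class(fit) <- c("gs_fit", class(fit))
  fit
}

#' @export
print.gs_fit <- function(x, ...) {
  cat("Genetic evaluation (", x$mode, "): ", x$str$n_ped, " animals, ",
      x$str$n_rec, " records, traits: ",
      paste(x$str$traits, collapse = ", "), "\n", sep = "")
  invisible(x)
}
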