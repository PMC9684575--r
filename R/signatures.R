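# 96-channel trinucleotide mutation catalogs and maximum-likelihood
# signature deconvolution by expectation-maximization.

#' Canonical 96-channel labels
#'
#' Pyrimidine-strand substitution classes (C>A, C>G, C>T, T>A, T>C, T>G)
#' crossed with 5' and 3' flanking bases, in the conventional order:
#' substitution class, then 5' base, then 3' base, each alphabetical.
#'
#' @return character vector of 96 labels like "A[C>A]A"
#' @export
catalog_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (f in bases) for (t in bases)
    out <- c(out, sprintf("%s[%s]%s", f, s, t))
  out
}

#' Build a 96-channel mutation catalog from SNVs
#'
#' Each single-nucleotide variant is assigned to its trinucleotide-context
#' channel; purine-reference substitutions are reverse-complemented onto the
#' pyrimidine strand. Variants whose flanking base is unavailable (contig
#' edge) or whose reference base mismatches the sequence are skipped with a
#' message; otherwise counts conserve the number of input SNVs.
#'
#' @param snvs data.frame with columns contig, pos, ref, alt (single bases)
#' @param reference named character vector (or list) of contig sequences
#' @return named integer vector of class `MutationCatalog96` (length 96)
#' @export
build_catalog <- function(snvs, reference) {
  channels <- catalog_channels()
  counts <- stats::setNames(integer(96), channels)
  pyr <- c("C", "T")
  for (i in seq_len(nrow(snvs))) {
    ref <- toupper(snvs$ref[i]); alt <- toupper(snvs$alt[i])
    if (nchar(ref) != 1 || nchar(alt) != 1) stop("not a single-base substitution")
    seq <- reference[[snvs$contig[i]]]
    if (is.null(seq)) stop("unknown contig: ", snvs$contig[i])
    pos <- snvs$pos[i]
    if (pos <= 1 || pos >= nchar(seq)) {
      message(sprintf("SNV at %s:%d skipped: flank unavailable",
                      snvs$contig[i], pos))
      next
    }
    tri <- toupper(substr(seq, pos - 1, pos + 1))
    if (substr(tri, 2, 2) != ref)
      stop(sprintf("SNV ref %s inconsistent with reference at %s:%d",
                   ref, snvs$contig[i], pos))
    if (!ref %in% pyr) {
      tri <- revcomp(tri); ref <- chartr("AG", "TC", ref)
      alt <- chartr("ACGT", "TGCA", alt)
    }
    key <- sprintf("%s[%s>%s]%s", substr(tri, 1, 1), ref, alt,
                   substr(tri, 3, 3))
    counts[key] <- counts[key] + 1L
  }
  structure(counts, class = "MutationCatalog96")
}

#' Validate a signature matrix
#'
#' @param sigs numeric matrix, 96 rows (channels) x K columns (signatures);
#'   each column sums to 1
#' @return the matrix, with canonical rownames if absent
#' @export
signature_matrix <- function(sigs) {
  sigs <- as.matrix(sigs)
  if (nrow(sigs) != 96) stop("signature matrix must have 96 rows")
  if (any(sigs < 0)) stop("signature probabilities must be >= 0")
  if (any(abs(colSums(sigs) - 1) > 1e-6))
    stop("each signature must sum to 1")
  if (is.null(rownames(sigs))) rownames(sigs) <- catalog_channels()
  if (is.null(colnames(sigs)))
    colnames(sigs) <- paste0("Signature.", seq_len(ncol(sigs)))
  sigs
}

#' Maximum-likelihood signature deconvolution (EM)
#'
#' Finds the mixture weights on the simplex maximizing the multinomial
#' log-likelihood sum_c x_c * log(sum_k w_k S_kc) by expectation-
#' maximization from a uniform start. The EM update
#' `w_k <- w_k * sum_c x_c S_kc / (sum_j w_j S_jc) / N` is monotone in the
#' likelihood; iteration stops when the gain drops below `tol`.
#'
#' @param catalog a [build_catalog()] vector (96 non-negative counts,
#'   total > 0)
#' @param sigs a [signature_matrix()]
#' @param tol convergence tolerance on the log-likelihood gain
#'   (default 1e-8)
#' @param max_iter iteration cap (default 10000)
#' @return list of class `SignatureFit`: weights (named, on the simplex),
#'   log_likelihood, n_mutations, n_iter, ll_trace
#' @export
fit_signature_weights <- function(catalog, sigs, tol = 1e-8,
                                  max_iter = 10000L) {
  sigs <- signature_matrix(sigs)
  x <- as.numeric(catalog)
  if (length(x) != 96) stop("catalog must have 96 channels")
  N <- sum(x)
  if (N == 0) stop("empty catalog")
  K <- ncol(sigs)
  obs <- x > 0
  if (any(rowSums(sigs[obs, , drop = FALSE]) == 0))
    stop("observed channel with zero mass under every signature")

  w <- rep(1 / K, K)
  xo <- x[obs]
  S <- sigs[obs, , drop = FALSE]           # only observed channels matter
  ll <- function(w) sum(xo * log(as.numeric(S %*% w)))
  ll_trace <- ll(w)
  for (it in seq_len(max_iter)) {
    p <- as.numeric(S %*% w)
    w_new <- w * as.numeric(crossprod(S, xo / p)) / N
    ll_new <- ll(w_new)
    ll_trace <- c(ll_trace, ll_new)
    gain <- ll_new - ll_trace[length(ll_trace) - 1L]
    w <- w_new
    if (gain < tol) break
  }
  w <- w / sum(w)
  structure(list(weights = stats::setNames(w, colnames(sigs)),
                 log_likelihood = ll(w), n_mutations = N,
                 n_iter = length(ll_trace) - 1L, ll_trace = ll_trace),
            class = "SignatureFit")
}

#' Extract a named signature's fitted fraction
#'
#' @param fit a [fit_signature_weights()] result
#' @param name signature name
#' @return the fitted weight
#' @export
signature_fraction <- function(fit, name) {
  if (!name %in% names(fit$weights)) stop("unknown signature: ", name)
  unname(fit$weights[name])
}

#' @method print SignatureFit
#' @export
print.SignatureFit <- function(x, ...) {
  cat(sprintf("SignatureFit: %d mutations, logL %.3f, %d EM iterations\n",
              x$n_mutations, x$log_likelihood, x$n_iter))
  w <- sort(x$weights, decreasing = TRUE)
  w <- w[w > 0.005]
  for (nm in names(w)) cat(sprintf("  %-16s %.3f\n", nm, w[nm]))
  invisible(x)
}
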