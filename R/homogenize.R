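## Step 3: iterative homogenization of confidences over the contact graph.

#' Homogenize confidences over structural neighbourhoods
#'
#' Iterates, simultaneously for every non-excluded residue,
#' \deqn{\rho_i^{(t+1)} = \frac{\rho_i^{(0)} + \sum_{j} \phi(d_{ij})\,
#'   \rho_j^{(t)}}{1 + \sum_{j} \phi(d_{ij})}}
#' where the sums run over the non-excluded neighbours within the kernel
#' cutoff and \eqn{\rho^{(0)}} is the starting confidence from the
#' attribution/inference steps. Each residue is anchored to its own
#' starting value with unit weight, which preserves contrast between
#' regions while pulling neighbours together, so convergence produces
#' blocks of residues with similar confidences rather than a single global
#' consensus. Iteration stops when the RMSD between consecutive vectors
#' (over non-excluded residues) falls below \code{tol}.
#'
#' The update is a linear fixed-point iteration whose iteration matrix has
#' spectral radius < 1 (each row's neighbour weights sum to strictly less
#' than its denominator), so it converges for any input; the cap
#' \code{maxIter} only guards against a misconfigured tolerance.
#'
#' @param conf [ConfidenceVector-class] with a confidence for every
#'   non-excluded residue.
#' @param dmat distance matrix from [ensembleDistances()].
#' @param kernel a [SigmoidKernel-class].
#' @param tol convergence RMSD (default 1e-5).
#' @param maxIter iteration cap (default 1e5).
#' @return the converged [ConfidenceVector-class] (statuses preserved)
#'   with attribute \code{"iterations"} set to the number of iterations
#'   performed.
#' @examples
#' ## two residues 3.75 A apart (phi = 0.5), starting at +1 / -1,
#' ## converge to +0.5 / -0.5
#' dm <- matrix(c(0, 3.75, 3.75, 0), 2,
#'              dimnames = list(c("A:1", "A:2"), c("A:1", "A:2")))
#' cv <- new("ConfidenceVector", rho = c("A:1" = 1, "A:2" = -1),
#'           status = c("A:1" = "measured", "A:2" = "measured"))
#' confidences(homogenizeConfidences(cv, dm))
#' @export
homogenizeConfidences <- function(conf, dmat, kernel = sigmoidKernel(),
                                  tol = 1e-5, maxIter = 1e5) {
    act <- names(conf@rho)[conf@status != "excluded"]
    if (length(act) == 0L) stop("no non-excluded residues to homogenize")
    if (!all(act %in% rownames(dmat)))
        stop("distance matrix does not cover all residues")
    w <- .phiMatrix(dmat[act, act, drop = FALSE], kernel)
    rho0 <- conf@rho[act]
    denom <- 1 + rowSums(w)
    rho <- rho0
    iter <- 0L
    repeat {
        rhoNew <- (rho0 + as.vector(w %*% rho)) / denom
        iter <- iter + 1L
        rmsd <- sqrt(mean((rhoNew - rho)^2))
        rho <- rhoNew
        if (rmsd < tol) break
        if (iter >= maxIter)
            stop("homogenization did not converge within ", maxIter,
                 " iterations (last RMSD ", format(rmsd), ")")
    }
    out <- conf@rho
    out[act] <- rho
    res <- new("ConfidenceVector", rho = out, status = conf@status)
    attr(res, "iterations") <- iter
    res
}
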