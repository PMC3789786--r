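## Optimization engine: FBA, FVA, knockouts, blocked reactions.
##
## Numerical policy: steady state enforced to 1e-6, bound feasibility
## 1e-7, zero-flux threshold 1e-6. Unbounded directions are clamped to
## +/- 1000 mmol/(gDW h) before solving. Alternate optima are the rule
## in these models, so headline analyses work from FVA extremes rather
## than a single flux vector.

DEFAULT_BIG <- 1000
ZERO_TOL <- 1e-6

.lp_data <- function(model, big = DEFAULT_BIG) {
    S <- as.matrix(model@stoichiometry)
    lb <- pmax(model@reactions$lb, -big)
    ub <- pmin(model@reactions$ub, big)
    obj <- numeric(ncol(S))
    obj[match(model@objective, model@reactions$id)] <- 1
    list(S = S, lb = lb, ub = ub, obj = obj, ids = model@reactions$id)
}

.lp_status <- c("0" = "optimal", "1" = "infeasible", "2" = "unbounded",
                "3" = "solver_failure")

.lp_solve <- function(A, b, c, lb, ub, maximize = TRUE,
                      backend = c("dense", "boot")) {
    backend <- match.arg(backend)
    if (backend == "dense") {
        r <- .simplex_lp(A, b, c, lb, ub, maximize)
        return(list(status = .lp_status[[as.character(r$status)]],
                    obj = r$obj, x = r$x))
    }
    .lp_boot(A, b, c, lb, ub, maximize)
}

## Reference backend: two-phase tableau simplex from the boot package,
## used as an independent cross-check. Variables are shifted to z >= 0.
.lp_boot <- function(A, b, c, lb, ub, maximize = TRUE) {
    if (!requireNamespace("boot", quietly = TRUE))
        stop("backend 'boot' requires the boot package")
    n <- length(c)
    beq <- b - as.vector(A %*% lb)
    Aeq <- A
    neg <- beq < 0
    Aeq[neg, ] <- -Aeq[neg, , drop = FALSE]
    beq[neg] <- -beq[neg]
    span <- ub - lb
    r <- tryCatch(
        boot::simplex(a = if (maximize) c else -c,
                      A1 = diag(n), b1 = span,
                      A3 = Aeq, b3 = beq, maxi = TRUE,
                      n.iter = 50 * (n + nrow(A))),
        error = function(e) NULL)
    if (is.null(r))
        return(list(status = "solver_failure", obj = NA_real_,
                    x = numeric(0)))
    if (r$solved == -1)
        return(list(status = "infeasible", obj = NA_real_, x = numeric(0)))
    if (r$solved != 1)
        return(list(status = "solver_failure", obj = NA_real_, x = numeric(0)))
    x <- as.numeric(r$soln) + lb
    list(status = "optimal", obj = sum(c * x), x = x)
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction's flux subject to steady state
#' (S v = 0 for every metabolite) and the flux bounds. A feasible
#' problem whose optimum is zero growth returns status "optimal" with
#' objective 0; infeasibility (e.g. maintenance demands that cannot be
#' met) is reported as such.
#'
#' @param model a [MetabolicModel-class] with an objective set.
#' @param backend "dense" (the package's bounded-variable simplex) or
#'   "boot" (reference tableau simplex from the boot package).
#' @param big replacement magnitude for infinite bounds, mmol/(gDW h).
#' @param solution a FluxSolution (for the accessors).
#' @return a [FluxSolution-class].
#' @examples
#' m <- exampleChainModel()
#' solveFBA(m)
#' @export
solveFBA <- function(model, backend = c("dense", "boot"),
                     big = DEFAULT_BIG) {
    backend <- match.arg(backend)
    lp <- .lp_data(model, big)
    r <- .lp_solve(lp$S, numeric(nrow(lp$S)), lp$obj, lp$lb, lp$ub,
                   maximize = TRUE, backend = backend)
    if (r$status != "optimal")
        return(new("FluxSolution", status = r$status,
                   objectiveValue = NA_real_, fluxes = numeric(0)))
    new("FluxSolution", status = "optimal", objectiveValue = r$obj,
        fluxes = stats::setNames(r$x, lp$ids))
}

#' Flux variability analysis at (a fraction of) optimal growth
#'
#' Per reaction, minimizes and maximizes its flux under the additional
#' constraint that the objective stays at or above
#' \code{fractionOfOptimum} times its optimum. The objective-fixing row
#' is added once and one LP is solved per reaction per direction, in
#' deterministic order.
#'
#' @inheritParams solveFBA
#' @param fractionOfOptimum fraction of the FBA optimum to enforce
#'   (default 1, i.e. the optimal face). Use 0 for no growth constraint.
#' @param reactions reaction ids to analyze (default: all).
#' @return data.frame with columns \code{id}, \code{min}, \code{max}.
#' @export
fluxVariability <- function(model, fractionOfOptimum = 1, reactions = NULL,
                            backend = c("dense", "boot"), big = DEFAULT_BIG) {
    backend <- match.arg(backend)
    lp <- .lp_data(model, big)
    sol <- solveFBA(model, backend = backend, big = big)
    if (sol@status != "optimal")
        stop("FVA requires an optimal FBA solution; status was ", sol@status)
    if (is.null(reactions)) reactions <- lp$ids
    idx <- match(reactions, lp$ids)
    if (anyNA(idx)) stop("unknown reaction id(s): ",
                         paste(reactions[is.na(idx)], collapse = ", "))
    ## augment with a slack column: c'v - s = 0, s in [f * opt, big^2]
    A <- rbind(cbind(lp$S, 0), c(lp$obj, -1))
    n <- length(lp$ids)
    lo <- c(lp$lb, fractionOfOptimum * sol@objectiveValue)
    hi <- c(lp$ub, max(big, sol@objectiveValue) * 10)
    b <- numeric(nrow(A))
    mn <- mx <- numeric(length(idx))
    for (k in seq_along(idx)) {
        cvec <- numeric(n + 1); cvec[idx[k]] <- 1
        rmin <- .lp_solve(A, b, cvec, lo, hi, maximize = FALSE, backend = backend)
        rmax <- .lp_solve(A, b, cvec, lo, hi, maximize = TRUE, backend = backend)
        if (rmin$status != "optimal" || rmax$status != "optimal")
            stop("FVA subproblem not optimal for ", lp$ids[idx[k]],
                 " (", rmin$status, "/", rmax$status, ")")
        mn[k] <- rmin$obj; mx[k] <- rmax$obj
    }
    data.frame(id = reactions, min = pmin(mn, mx), max = pmax(mn, mx),
               stringsAsFactors = FALSE)
}

#' Apply gene knockouts to a model
#'
#' Reactions whose GPR evaluates false with the given genes removed get
#' bounds (0, 0); everything else, including reactions with no known
#' gene, is untouched. The input model is not mutated.
#'
#' @param model a MetabolicModel.
#' @param genes character vector of gene ids to remove.
#' @return the constrained model copy.
#' @export
applyKnockouts <- function(model, genes) {
    unknown <- setdiff(genes, model@genes$id)
    if (length(unknown)) stop("unknown gene id(s): ",
                              paste(unknown, collapse = ", "))
    if (!length(genes)) return(model)
    hit <- vapply(model@reactions$gpr,
                  function(g) nzchar(g) && !gprEvaluate(g, removed = genes),
                  logical(1), USE.NAMES = FALSE)
    model@reactions$lb[hit] <- 0
    model@reactions$ub[hit] <- 0
    model
}

#' Reactions unable to carry flux under fully open exchanges
#'
#' Opens every exchange-tagged reaction in both directions, then runs
#' FVA with no growth constraint; reactions whose range collapses to
#' [0, 0] within tolerance can never be active and are returned.
#'
#' @inheritParams solveFBA
#' @param tol zero-flux threshold.
#' @return character vector of blocked reaction ids.
#' @export
blockedReactions <- function(model, tol = ZERO_TOL,
                             backend = c("dense", "boot"),
                             big = DEFAULT_BIG) {
    backend <- match.arg(backend)
    ex <- taggedReactions(model, "exchange")
    m2 <- setBounds(model, ex, lb = -big, ub = big)
    fva <- fluxVariability(m2, fractionOfOptimum = 0, backend = backend,
                           big = big)
    fva$id[abs(fva$min) < tol & abs(fva$max) < tol]
}

#' Verify that a flux solution satisfies steady state and bounds
#'
#' @param model the model the solution was computed on.
#' @param solution a FluxSolution with status "optimal".
#' @param ssTol steady-state tolerance on metabolite balances.
#' @param boundTol bound-feasibility tolerance.
#' @return TRUE invisibly; stops with a message otherwise.
#' @export
checkSolution <- function(model, solution, ssTol = 1e-6, boundTol = 1e-7) {
    stopifnot(solution@status == "optimal")
    v <- solution@fluxes[model@reactions$id]
    resid <- as.vector(model@stoichiometry %*% v)
    if (max(abs(resid)) > ssTol)
        stop("steady state violated: max residual ", max(abs(resid)))
    lb <- pmax(model@reactions$lb, -DEFAULT_BIG)
    ub <- pmin(model@reactions$ub, DEFAULT_BIG)
    if (any(v < lb - boundTol) || any(v > ub + boundTol))
        stop("flux bound violated")
    invisible(TRUE)
}
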