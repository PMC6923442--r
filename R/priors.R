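#' Prior specification for demographic and mutation parameters
#'
#' Each parameter gets a distribution (`"unif"` or `"logunif"`) with
#' finite bounds; cross-parameter order constraints (e.g. `"t2 < t1"`)
#' are enforced by rejection at sampling time.  Units: effective sizes in
#' diploid individuals, times and durations in generations, mutation
#' rates per locus per generation.
#'
#' @param params named list; each element `list(dist, min, max)`.
#' @param constraints character vector of R comparison expressions over
#'   parameter names.
#' @return a `prior_spec`.
#' @export
prior_spec <- function(params, constraints = character()) {
  for (nm in names(params)) {
    p <- params[[nm]]
    stopifnot(p$dist %in% c("unif", "logunif"),
              is.finite(p$min), is.finite(p$max), p$min <= p$max)
    if (p$dist == "logunif" && p$min <= 0)
      stop("log-uniform prior needs positive bounds: ", nm)
  }
  structure(list(params = params, constraints = constraints),
            class = "prior_spec")
}

#' Default broad priors for the three-deme invasion scenarios
#'
#' Step 1 of the two-step analysis uses broad priors for topology
#' choice; `step2 = TRUE` restricts the first arrival to at most 10
#' generations ago and tightens event times, reflecting field knowledge
#' that the first outbreak is recent.
#'
#' @param step2 use the restricted second-step priors.
#' @return a [prior_spec()].
#' @export
default_priors <- function(step2 = FALSE) {
  N <- function(lo = 10, hi = 10000) list(dist = "logunif", min = lo, max = hi)
  U <- function(lo, hi) list(dist = "unif", min = lo, max = hi)
  params <- list(
    N_Ma1 = N(), N_Ma2 = N(), N_Br = N(), N_SRC = N(100, 10000),
    Nb_Ma1 = U(2, 200), Nb_Ma2 = U(2, 200), Nb_Br = U(2, 200),
    db_Ma1 = U(1, 5), db_Ma2 = U(1, 5), db_Br = U(1, 5),
    t1 = if (step2) U(2, 10) else U(1, 50),
    t2 = if (step2) U(1, 9) else U(1, 50),
    t3 = if (step2) U(1, 9) else U(1, 50),
    mu_mean = U(1e-4, 1e-3),
    gsm_p = U(0, 0.3))
  prior_spec(params,
             constraints = c("t2 < t1", "t3 < t1", "db_Ma1 < t1",
                             "db_Ma2 < t2", "db_Br < t3"))
}

#' Draw parameter vectors from a prior specification
#'
#' Rejection sampling against the cross-parameter constraints, with a
#' retry cap; an unsatisfiable constraint set raises an error.
#'
#' @param priors a [prior_spec()].
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @param max_tries rejection cap per draw (default 1000).
#' @return data.frame of `n` rows, one column per parameter.
#' @export
sample_prior <- function(priors, n = 1, seed = NULL, max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  nm <- names(priors$params)
  draw1 <- function() {
    for (tries in seq_len(max_tries)) {
      x <- vapply(priors$params, function(p) {
        if (p$dist == "unif") runif(1, p$min, p$max)
        else exp(runif(1, log(p$min), log(p$max)))
      }, numeric(1))
      env <- as.list(x)
      ok <- all(vapply(priors$constraints, function(cst)
        isTRUE(eval(parse(text = cst), envir = env)), logical(1)))
      if (ok) return(x)
    }
    stop("prior constraints rejected ", max_tries,
         " consecutive draws; constraint set may be unsatisfiable")
  }
  out <- as.data.frame(t(vapply(seq_len(n), function(i) draw1(),
                                numeric(length(nm)))))
  names(out) <- nm
  out
}
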