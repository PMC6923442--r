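#' Parse a demographic scenario from its event-list text
#'
#' Scenarios are written in a small line-oriented grammar (one statement
#' per line, `#` comments allowed):
#' \preformatted{
#' scenario SC5
#' deme Ma1 size N_Ma1
#' deme Ma2 size N_Ma2
#' deme Br  size N_Br
#' deme SRC size N_SRC ancestral
#' event found Ma1 from SRC at t1 founder Nb_Ma1 duration db_Ma1
#' event found Ma2 from Ma1 at t2 founder Nb_Ma2 duration db_Ma2
#' event found Br  from Ma1 at t3 founder Nb_Br  duration db_Br
#' constraint t2 < t1
#' constraint t3 < t1
#' }
#' Each non-ancestral deme must be founded exactly once, and following
#' founding sources must reach the single ancestral deme (so the
#' coalescent always finds a common deme).  Size/time symbols are bound
#' to priors or constants at simulation time.  Founding semantics,
#' backwards in time: the derived deme has its contemporary size `N`
#' until `t - duration`, the founder bottleneck size `Nb` on
#' `(t - duration, t)`, and at `t` all its lineages move to the source
#' deme.
#'
#' @param spec_text scenario text (single string or character vector of
#'   lines).
#' @return a `demographic_scenario` list: `name`, `demes`, `ancestral`,
#'   `sizes` (deme -> symbol), `events` (data.frame), `constraints`.
#' @export
parse_scenario <- function(spec_text) {
  lines <- unlist(strsplit(spec_text, "\n"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  name <- NULL; demes <- character(); sizes <- character()
  ancestral <- character()
  ev <- list(); constraints <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\\s+")[[1]]
    kw <- tok[1]
    if (kw == "scenario") {
      name <- tok[2]
    } else if (kw == "deme") {
      if (length(tok) < 4 || tok[3] != "size")
        stop("scenario parse error: bad deme statement: ", lines[i])
      demes <- c(demes, tok[2])
      sizes[tok[2]] <- tok[4]
      if (length(tok) >= 5 && tok[5] == "ancestral")
        ancestral <- c(ancestral, tok[2])
    } else if (kw == "event") {
      # handled in the dedicated pass below
    } else if (kw == "constraint") {
      expr <- paste(tok[-1], collapse = " ")
      if (nzchar(expr)) constraints <- c(constraints, expr)
    } else {
      stop("scenario parse error: unknown statement: ", lines[i])
    }
  }
  ev <- list()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\\s+")[[1]]
    if (tok[1] != "event") next
    if (length(tok) != 11 || tok[2] != "found" || tok[4] != "from" ||
        tok[6] != "at" || tok[8] != "founder" || tok[10] != "duration")
      stop("scenario parse error: bad event statement: ", lines[i])
    ev[[length(ev) + 1]] <- data.frame(
      derived = tok[3], source = tok[5], time = tok[7],
      founder = tok[9], duration = tok[11], stringsAsFactors = FALSE)
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(derived = character(), source = character(),
               time = character(), founder = character(),
               duration = character())
  if (is.null(name)) stop("scenario parse error: missing scenario name")
  if (length(ancestral) != 1)
    stop("scenario parse error: exactly one ancestral deme required")
  for (d in setdiff(demes, ancestral)) {
    k <- sum(events$derived == d)
    if (k == 0)
      stop("scenario parse error: deme ", d,
           " is never founded (orphan deme, no path to ", ancestral, ")")
    if (k > 1)
      stop("scenario parse error: deme ", d, " founded twice")
  }
  if (any(events$derived == ancestral))
    stop("scenario parse error: ancestral deme cannot be founded")
  # every deme must reach the ancestral deme through founding sources
  for (d in setdiff(demes, ancestral)) {
    cur <- d; seen <- character()
    while (cur != ancestral) {
      if (cur %in% seen)
        stop("scenario parse error: founding cycle at deme ", cur)
      seen <- c(seen, cur)
      nxt <- events$source[events$derived == cur]
      if (!length(nxt) || !nxt %in% demes)
        stop("scenario parse error: deme ", d, " never merges into ",
             ancestral, " (event 'found ", cur, "')")
      cur <- nxt
    }
  }
  structure(list(name = name, demes = demes, ancestral = ancestral,
                 sizes = sizes, events = events,
                 constraints = constraints),
            class = "demographic_scenario")
}

#' Render a scenario back to its text form
#'
#' `parse_scenario(format_scenario(s))` reproduces `s`.
#'
#' @param s a `demographic_scenario`.
#' @return single string of scenario text.
#' @export
format_scenario <- function(s) {
  out <- paste("scenario", s$name)
  for (d in s$demes)
    out <- c(out, paste("deme", d, "size", s$sizes[[d]],
                        if (d == s$ancestral) "ancestral" else NULL))
  for (i in seq_len(nrow(s$events)))
    out <- c(out, with(s$events[i, ],
      paste("event found", derived, "from", source, "at", time,
            "founder", founder, "duration", duration)))
  for (cst in s$constraints) out <- c(out, paste("constraint", cst))
  paste(out, collapse = "\n")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat(format_scenario(x), "\n")
  invisible(x)
}

#' Default six-scenario family for a three-deme invasion history
#'
#' Six topologies describing how three sampled demes (`Ma1`, `Ma2`,
#' `Br`) may descend from one unsampled source (`SRC`): serial chains,
#' radiations from each deme, and three independent introductions.
#' `SC5` is the radiation from `Ma1` (first `Ma1` from the source, then
#' `Ma2` and `Br` independently from `Ma1`).  All are expressed in the
#' scenario grammar, so alternative topologies can be substituted as
#' text.
#'
#' @return named list of `demographic_scenario` objects (`SC1`..`SC6`).
#' @export
default_scenarios <- function() {
  base <- function(name, ev, cst) {
    parse_scenario(paste(c(
      paste("scenario", name),
      "deme Ma1 size N_Ma1",
      "deme Ma2 size N_Ma2",
      "deme Br size N_Br",
      "deme SRC size N_SRC ancestral",
      ev, if (length(cst)) paste("constraint", cst)), collapse = "\n"))
  }
  list(
    SC1 = base("SC1", c(   # serial Ma1 -> Ma2 -> Br
      "event found Ma1 from SRC at t1 founder Nb_Ma1 duration db_Ma1",
      "event found Ma2 from Ma1 at t2 founder Nb_Ma2 duration db_Ma2",
      "event found Br from Ma2 at t3 founder Nb_Br duration db_Br"),
      c("t2 < t1", "t3 < t2")),
    SC2 = base("SC2", c(   # serial Ma1 -> Br -> Ma2
      "event found Ma1 from SRC at t1 founder Nb_Ma1 duration db_Ma1",
      "event found Br from Ma1 at t3 founder Nb_Br duration db_Br",
      "event found Ma2 from Br at t2 founder Nb_Ma2 duration db_Ma2"),
      c("t3 < t1", "t2 < t3")),
    SC3 = base("SC3", c(   # radiation from Br
      "event found Br from SRC at t1 founder Nb_Br duration db_Br",
      "event found Ma1 from Br at t2 founder Nb_Ma1 duration db_Ma1",
      "event found Ma2 from Br at t3 founder Nb_Ma2 duration db_Ma2"),
      c("t2 < t1", "t3 < t1")),
    SC4 = base("SC4", c(   # radiation from Ma2
      "event found Ma2 from SRC at t1 founder Nb_Ma2 duration db_Ma2",
      "event found Ma1 from Ma2 at t2 founder Nb_Ma1 duration db_Ma1",
      "event found Br from Ma2 at t3 founder Nb_Br duration db_Br"),
      c("t2 < t1", "t3 < t1")),
    SC5 = base("SC5", c(   # radiation from Ma1
      "event found Ma1 from SRC at t1 founder Nb_Ma1 duration db_Ma1",
      "event found Ma2 from Ma1 at t2 founder Nb_Ma2 duration db_Ma2",
      "event found Br from Ma1 at t3 founder Nb_Br duration db_Br"),
      c("t2 < t1", "t3 < t1")),
    SC6 = base("SC6", c(   # three independent introductions
      "event found Ma1 from SRC at t1 founder Nb_Ma1 duration db_Ma1",
      "event found Ma2 from SRC at t2 founder Nb_Ma2 duration db_Ma2",
      "event found Br from SRC at t3 founder Nb_Br duration db_Br"),
      character(0)))
}
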