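# Policy timelines: per-family annual levels, coverage fractions and
# enforcement scores, plus the real cigarette price series. Every
# year-keyed series is a step function: the value at year y is the entry
# at the latest year <= y (levels persist until changed).

is_year_names <- function(x) {
  !is.null(names(x)) && length(x) > 0 && all(grepl("^[0-9]{4}$", names(x)))
}

# step-function lookup in a year-named vector
tl_at <- function(series, year, what = "policy") {
  if (is.null(series) || !length(series)) {
    stop("no ", what, " defined in the timeline")
  }
  yrs <- as.integer(names(series))
  ok <- yrs <= year
  if (!any(ok)) {
    stop("no ", what, " defined at or before year ", year)
  }
  series[[which(yrs == max(yrs[ok]))[1L]]]
}

# step-function lookup in a year-named list (e.g. marketing level mixes)
tl_at_list <- function(lst, year, what = "policy") {
  if (is.null(lst) || !length(lst)) stop("no ", what, " defined")
  yrs <- as.integer(names(lst))
  ok <- yrs <= year
  if (!any(ok)) stop("no ", what, " defined at or before year ", year)
  lst[[which(yrs == max(yrs[ok]))[1L]]]
}

#' Construct a policy timeline
#'
#' @param policies named list of per-family specifications (year-keyed
#'   level/coverage series plus scalar enforcement scores); see the shipped
#'   `mexico_2002_2018` preset for the full layout.
#' @param baseline_year the scenario baseline (counterfactual) year.
#' @param price year-named numeric vector of mean annual real cigarette
#'   prices.
#' @param nondaily_scale multiplier in [0, 1] applied to every policy
#'   effect size for nondaily smokers (1 = same effects as daily; 0.5 is
#'   the half-effect sensitivity setting).
#' @param price_symmetric apply negative shocks when real prices fall
#'   (default) instead of flooring the price effect at zero.
#' @param name label stored in results metadata.
#' @return object of class `policy_timeline`.
#' @export
policy_timeline <- function(policies, baseline_year, price = NULL,
                            nondaily_scale = 1, price_symmetric = TRUE,
                            name = "custom") {
  if (nondaily_scale < 0 || nondaily_scale > 1) {
    stop("nondaily_scale must be in [0, 1]")
  }
  if (!is.null(price)) {
    if (any(price <= 0)) stop("prices must be positive")
    if (!is_year_names(price)) stop("price series must be year-named")
  }
  structure(list(name = name, baseline_year = as.integer(baseline_year),
                 policies = policies, price = price,
                 nondaily_scale = nondaily_scale,
                 price_symmetric = price_symmetric),
            class = "policy_timeline")
}

#' @export
print.policy_timeline <- function(x, ...) {
  cat("<policy_timeline>", x$name, "- baseline", x$baseline_year,
      "-", length(x$policies), "policy families",
      if (!is.null(x$price)) "+ price series" else "", "\n")
  invisible(x)
}

# normalise the raw YAML tree: year-keyed scalar maps -> named vectors
normalise_series <- function(x) {
  if (is.list(x)) {
    if (is_year_names(x) && all(vapply(x, function(e)
        !is.list(e) && length(e) == 1L, logical(1L)))) {
      return(unlist(x))
    }
    return(lapply(x, normalise_series))
  }
  x
}

#' Read a policy timeline from a YAML file
#'
#' @param path YAML file laid out like the shipped `mexico_2002_2018.yaml`.
#' @return a [policy_timeline()].
#' @export
read_timeline <- function(path) {
  raw <- yaml::read_yaml(path)
  pol <- lapply(raw$policies, normalise_series)
  price <- if (!is.null(raw$price)) unlist(raw$price)
  policy_timeline(policies = pol,
                  baseline_year = raw$baseline_year,
                  price = price,
                  nondaily_scale = raw$nondaily_scale %||% 1,
                  price_symmetric = raw$price_symmetric %||% TRUE,
                  name = raw$name %||% basename(path))
}

#' The Mexico 2002-2018 policy timeline preset
#'
#' Encodes the implemented policy levels: health warnings low (2002),
#' moderate (2004), high (2010); smoke-free worksite coverage 10% in
#' 2008-09, 18% in 2010-13 and 45% from 2014, restaurant/bar coverage 60%
#' in 2010-12 and 70% from 2013, enforcement 4/10; a low-level media
#' campaign from 2005; marketing restrictions at 50% minimal (2002), 100%
#' minimal (2004) and 75% moderate + 25% minimal (2009), enforcement 5/10;
#' cessation treatment with pharmacotherapy available throughout, partial
#' financial coverage from 2007, a low-level quit line from 2008 and a 20%
#' brief-intervention index; youth access at low enforcement throughout.
#' The bundled price series is a synthetic stand-in for the unpublished
#' real-price data (see [synth_price_series()]).
#'
#' @param price optional year-named price vector overriding the bundled
#'   synthetic series.
#' @param nondaily_scale see [policy_timeline()].
#' @return a [policy_timeline()].
#' @export
mexico_timeline <- function(price = NULL, nondaily_scale = 1) {
  tl <- read_timeline(system.file("extdata", "mexico_2002_2018.yaml",
                                  package = "smokesim"))
  if (!is.null(price)) tl$price <- price
  tl$nondaily_scale <- nondaily_scale
  tl
}

# freeze one node of the policy tree at its baseline-year value
freeze_node <- function(x, baseline_year) {
  if (is.list(x)) {
    if (is_year_names(x)) {
      out <- list(tl_at_list(x, baseline_year))
      names(out) <- as.character(baseline_year)
      return(out)
    }
    return(lapply(x, freeze_node, baseline_year = baseline_year))
  }
  if (is_year_names(x)) {
    out <- x[1L]
    out[[1L]] <- tl_at(x, baseline_year)
    names(out) <- as.character(baseline_year)
    return(out)
  }
  x
}

#' Freeze a timeline at its baseline-year levels
#'
#' Produces the counterfactual timeline: every policy level, coverage and
#' the price are held at their baseline-year values for all years.
#'
#' @param timeline a [policy_timeline()].
#' @return a `policy_timeline` producing identity modifiers in every year.
#' @export
freeze_timeline <- function(timeline) {
  out <- timeline
  out$policies <- lapply(timeline$policies, freeze_node,
                         baseline_year = timeline$baseline_year)
  if (!is.null(out$price)) {
    p <- tl_at(out$price, timeline$baseline_year, "price")
    out$price <- stats::setNames(p, as.character(timeline$baseline_year))
  }
  out$name <- paste0(timeline$name, "_counterfactual")
  out
}

#' Keep one policy family active, freeze all others
#'
#' Used for single-policy attribution runs: the named family keeps its
#' actual timeline while every other family (including price unless
#' `family = "price"`) is frozen at baseline levels.
#'
#' @param timeline a [policy_timeline()].
#' @param family a policy family name, or `"price"`.
#' @return a `policy_timeline`.
#' @export
isolate_policy <- function(timeline, family) {
  if (!family %in% c(names(timeline$policies), "price")) {
    stop("unknown policy family: ", family)
  }
  out <- freeze_timeline(timeline)
  if (family == "price") {
    out$price <- timeline$price
  } else {
    out$policies[[family]] <- timeline$policies[[family]]
  }
  out$name <- paste0(timeline$name, "_only_", family)
  out
}
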