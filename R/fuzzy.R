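#' Training history of a runner
#'
#' The four practice-structure quantities consumed by the experience
#' scoring system: weekly training frequency and volume, years of running
#' practice, and the number of races entered.
#'
#' @param training_frequency Sessions per week (0-14).
#' @param training_volume Km per week (>= 0).
#' @param practice_time Years of practice (>= 0).
#' @param competitions Number of races (>= 0).
#' @return An object of class `training_history`.
#' @export
training_history <- function(training_frequency, training_volume,
                             practice_time, competitions) {
  h <- list(training_frequency = training_frequency,
            training_volume = training_volume,
            practice_time = practice_time,
            competitions = competitions)
  vals <- unlist(h)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("training history values must be finite and non-negative")
  if (training_frequency > 14)
    stop("training_frequency above 14 sessions/week is not plausible")
  structure(h, class = "training_history")
}

trapmf <- function(x, p) {
  # p = (a, b, c, d): 0 below a, ramps to 1 on [a,b], flat on [b,c],
  # ramps to 0 on [c,d]. Degenerate ramps (a == b) are vertical edges.
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]
  y <- numeric(length(x))
  y[x >= b & x <= cc] <- 1
  rise <- x > a & x < b
  if (b > a) y[rise] <- (x[rise] - a) / (b - a)
  fall <- x > cc & x < d
  if (d > cc) y[fall] <- (d - x[fall]) / (d - cc)
  y
}

validate_subsystem <- function(s, nm) {
  if (!all(c("inputs", "output", "rules") %in% names(s)))
    stop("fuzzy subsystem '", nm, "' needs inputs, output and rules")
  for (v in names(s$inputs)) {
    for (lv in s$inputs[[v]]$levels)
      if (length(lv) != 4 || is.unsorted(lv))
        stop("membership function for '", v, "' must be a sorted (a,b,c,d) trapezoid")
  }
  for (r in s$rules) {
    if (!all(names(r$`if`) %in% names(s$inputs)))
      stop("rule in '", nm, "' references unknown input")
    if (!r$then %in% names(s$output$levels))
      stop("rule in '", nm, "' references unknown output level '", r$then, "'")
  }
  s
}

#' Load a fuzzy rule base
#'
#' Reads the two-subsystem Mamdani configuration (membership functions
#' and rule tables) from YAML. The default file shipped with the package
#' anchors the linguistic levels to the group means of the cohort it was
#' designed around (e.g. "high" weekly volume centred at 55 km/wk);
#' users can substitute their own file with the same structure.
#'
#' @param path Path to a YAML rule base; `NULL` loads the packaged
#'   default.
#' @return A `fuzzy_rule_base` object with `quality` and `experience`
#'   subsystems.
#' @export
fuzzy_rule_base <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fuzzy_rules.yaml", package = "runexp")
  if (!file.exists(path)) stop("fuzzy rule base not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!all(c("quality", "experience") %in% names(cfg)))
    stop("rule base must define 'quality' and 'experience' subsystems")
  cfg$quality <- validate_subsystem(cfg$quality, "quality")
  cfg$experience <- validate_subsystem(cfg$experience, "experience")
  structure(cfg, class = "fuzzy_rule_base", source = path)
}

# Fuzzy inference over one subsystem.
#
# Two engines are provided. The default, "center-average", uses product
# conjunction, sum aggregation and the center-average defuzzifier (each
# rule contributes its consequent's centroid weighted by its firing
# strength). With the sum-to-one membership partitions used in the
# shipped rule base this reduces to multilinear interpolation of the
# consequent centroids over the input space, which makes the score
# provably monotone in every input whenever the rule table is monotone.
# The classic "mamdani" engine (min conjunction, max aggregation,
# centroid of the clipped-and-unioned output set) is retained as an
# option; it produces near-identical scores but admits small
# non-monotone wiggles near membership breakpoints.
mamdani_eval <- function(subsys, inputs,
                         method = c("center-average", "mamdani"),
                         n_grid = 1001) {
  method <- match.arg(method)
  # clamp inputs to their ranges so out-of-range saturates monotonically
  mu_in <- lapply(names(subsys$inputs), function(v) {
    spec <- subsys$inputs[[v]]
    x <- min(max(inputs[[v]], spec$range[1]), spec$range[2])
    vapply(spec$levels, function(p) trapmf(x, p), numeric(1))
  })
  names(mu_in) <- names(subsys$inputs)
  grid <- seq(subsys$output$range[1], subsys$output$range[2], length.out = n_grid)
  level_mf <- lapply(subsys$output$levels, function(p) trapmf(grid, p))
  if (method == "center-average") {
    centroids <- vapply(level_mf, function(mu) sum(mu * grid) / sum(mu), numeric(1))
    num <- 0; den <- 0
    for (r in subsys$rules) {
      w <- prod(vapply(names(r$`if`), function(v) mu_in[[v]][[r$`if`[[v]]]],
                       numeric(1)))
      num <- num + w * centroids[[r$then]]
      den <- den + w
    }
    if (den == 0) stop("no fuzzy rule fired; rule base does not cover the input space")
    return(num / den)
  }
  # classic Mamdani: per-level max firing strength, min implication,
  # max aggregation, centroid of the union
  strength <- stats::setNames(numeric(length(subsys$output$levels)),
                              names(subsys$output$levels))
  for (r in subsys$rules) {
    w <- min(vapply(names(r$`if`), function(v) mu_in[[v]][[r$`if`[[v]]]],
                    numeric(1)))
    if (w > strength[[r$then]]) strength[[r$then]] <- w
  }
  agg <- numeric(n_grid)
  for (lv in names(level_mf))
    agg <- pmax(agg, pmin(strength[[lv]], level_mf[[lv]]))
  tot <- sum(agg)
  if (tot == 0) stop("no fuzzy rule fired; rule base does not cover the input space")
  sum(agg * grid) / tot
}

#' Quality-of-practice score
#'
#' First Mamdani subsystem: training frequency and weekly volume are
#' fuzzified into the linguistic levels too low / low / medium / high,
#' combined through the rule table, and defuzzified by centroid into a
#' 0-10 quality-of-practice score.
#'
#' @param history A [training_history()].
#' @param rules A [fuzzy_rule_base()]; defaults to the packaged rule base.
#' @param method Inference engine, `"center-average"` (default, monotone)
#'   or `"mamdani"` (classic min/max/centroid).
#' @return Quality score in \[0, 10\].
#' @export
score_quality <- function(history, rules = fuzzy_rule_base(),
                          method = c("center-average", "mamdani")) {
  stopifnot(inherits(history, "training_history"))
  mamdani_eval(rules$quality,
               list(training_frequency = history$training_frequency,
                    training_volume = history$training_volume),
               method = method)
}

#' Running experience score and class label
#'
#' Chains the quality-of-practice score into the second Mamdani
#' subsystem together with the number of competitions and years of
#' practice, producing the final 0-10 experience score `x` and the
#' three-class label: less experienced (x < 5), moderately experienced
#' (5 <= x <= 7), experienced (x > 7).
#'
#' @inheritParams score_quality
#' @return List with `quality_of_practice`, `score` (x) and `label`.
#' @export
score_experience <- function(history, rules = fuzzy_rule_base(),
                             method = c("center-average", "mamdani")) {
  q <- score_quality(history, rules, method)
  x <- mamdani_eval(rules$experience,
                    list(quality_of_practice = q,
                         competitions = history$competitions,
                         practice_time = history$practice_time),
                    method = method)
  list(quality_of_practice = q, score = x, label = classify_score(x))
}

#' Experience class from a fuzzy score
#'
#' Pure threshold mapping, total on \[0, 10\]: less experienced below 5,
#' moderately experienced on the closed band \[5, 7\], experienced above 7.
#'
#' @param x Experience score(s) in \[0, 10\].
#' @return Factor with levels `less`, `moderate`, `experienced`.
#' @export
classify_score <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 10))
    stop("experience score must lie in [0, 10]")
  lab <- ifelse(x < 5, "less", ifelse(x <= 7, "moderate", "experienced"))
  factor(lab, levels = experience_levels())
}

#' The three experience class labels, in increasing order
#' @return Character vector `c("less", "moderate", "experienced")`.
#' @export
experience_levels <- function() c("less", "moderate", "experienced")

#' Score a cohort metadata table
#'
#' Applies [score_experience()] row-wise to a cohort metadata data frame
#' (columns `training_frequency`, `training_volume_km`, `years_practice`,
#' `n_races`), appending `quality_of_practice`, `experience_score` and
#' `experience_label` columns.
#'
#' @param metadata Data frame in the cohort metadata schema.
#' @param rules A [fuzzy_rule_base()].
#' @return The metadata with three score columns appended.
#' @export
score_cohort <- function(metadata, rules = fuzzy_rule_base(),
                         method = c("center-average", "mamdani")) {
  need <- c("training_frequency", "training_volume_km", "years_practice", "n_races")
  if (!all(need %in% names(metadata)))
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  scores <- lapply(seq_len(nrow(metadata)), function(i) {
    h <- training_history(metadata$training_frequency[i],
                          metadata$training_volume_km[i],
                          metadata$years_practice[i],
                          metadata$n_races[i])
    score_experience(h, rules, method)
  })
  metadata$quality_of_practice <- vapply(scores, `[[`, numeric(1), "quality_of_practice")
  metadata$experience_score <- vapply(scores, `[[`, numeric(1), "score")
  metadata$experience_label <- factor(vapply(scores, function(s) as.character(s$label),
                                             character(1)),
                                      levels = experience_levels())
  metadata
}
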