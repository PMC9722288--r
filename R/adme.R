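# Drug-likeness rule filters and gastrointestinal-absorption classification.
#
# Five descriptor-threshold rules (Lipinski, Ghose, Veber, Egan, Muegge) are
# evaluated with per-rule violation accounting, GI absorption is classified
# by an ellipse in (TPSA, WLOGP) space, and the combined "superior property"
# screen retains compounds with
#   (1) high GI absorption,
#   (2) 4 or 5 rules answering YES, and
#   (3) zero violations summed over the YES rules.

adme_rules <- c("lipinski", "ghose", "veber", "egan", "muegge")

#' Default drug-likeness rule thresholds
#'
#' The published descriptor-threshold definitions of the five filters.
#' Lipinski passes with at most one violated sub-condition; the other four
#' require all sub-conditions to hold. Every threshold is overridable.
#'
#' @return Nested named list of thresholds, one entry per rule.
#' @export
default_rule_thresholds <- function() {
  list(
    lipinski = list(mw_max = 500, mlogp_max = 4.15, hbd_max = 5, hba_max = 10,
                    max_violations = 1L),
    ghose = list(mw_min = 160, mw_max = 480, wlogp_min = -0.4, wlogp_max = 5.6,
                 mr_min = 40, mr_max = 130, atoms_min = 20, atoms_max = 70,
                 max_violations = 0L),
    veber = list(rotb_max = 10, tpsa_max = 140, max_violations = 0L),
    egan = list(wlogp_max = 5.88, tpsa_max = 131.6, max_violations = 0L),
    muegge = list(mw_min = 200, mw_max = 600, xlogp_min = -2, xlogp_max = 5,
                  tpsa_max = 150, rings_max = 7, carbons_min = 5,
                  heteroatoms_min = 2, rotb_max = 15, hba_max = 10,
                  hbd_max = 5, max_violations = 0L)
  )
}

# Vectorized sub-condition failure matrix for one rule over a descriptor
# table; returns an integer vector of violation counts.
rule_violations <- function(rule, d, th) {
  t <- th[[rule]]
  fails <- switch(
    rule,
    lipinski = cbind(d$mw > t$mw_max, d$mlogp > t$mlogp_max,
                     d$hbd > t$hbd_max, d$hba > t$hba_max),
    ghose = cbind(d$mw < t$mw_min | d$mw > t$mw_max,
                  d$wlogp < t$wlogp_min | d$wlogp > t$wlogp_max,
                  d$mr < t$mr_min | d$mr > t$mr_max,
                  d$total_atoms < t$atoms_min | d$total_atoms > t$atoms_max),
    veber = cbind(d$rotb > t$rotb_max, d$tpsa > t$tpsa_max),
    egan = cbind(d$wlogp > t$wlogp_max, d$tpsa > t$tpsa_max),
    muegge = cbind(d$mw < t$mw_min | d$mw > t$mw_max,
                   d$xlogp < t$xlogp_min | d$xlogp > t$xlogp_max,
                   d$tpsa > t$tpsa_max, d$rings > t$rings_max,
                   d$carbons < t$carbons_min,
                   d$heteroatoms < t$heteroatoms_min,
                   d$rotb > t$rotb_max, d$hba > t$hba_max, d$hbd > t$hbd_max),
    np_stop("np_config_error", "unknown rule '%s'", rule)
  )
  as.integer(rowSums(fails))
}

#' Evaluate one drug-likeness rule
#'
#' @param rule_name One of `"lipinski"`, `"ghose"`, `"veber"`, `"egan"`,
#'   `"muegge"`.
#' @param d Descriptor vector: named list or one-row data frame with the
#'   fields the rule consumes.
#' @param thresholds Rule-threshold configuration,
#'   see [default_rule_thresholds()].
#' @return List with `rule`, `passed` (within the rule's violation
#'   allowance) and `violations` (number of failed sub-conditions).
#' @export
evaluate_rule <- function(rule_name, d, thresholds = default_rule_thresholds()) {
  if (!rule_name %in% names(thresholds)) {
    np_stop("np_config_error", "unknown rule '%s'", rule_name)
  }
  d <- as_tibble(as.list(d))
  v <- rule_violations(rule_name, d, thresholds)
  list(rule = rule_name, passed = v <= thresholds[[rule_name]]$max_violations,
       violations = v)
}

#' Default gastrointestinal-absorption ellipse
#'
#' Parameters of the calibrated high-absorption ellipse in
#' (TPSA, WLOGP) space: center, semi-axes (TPSA and WLOGP directions before
#' rotation) and rotation angle in radians. Carried in configuration, not
#' hard-coded into the classifier.
#'
#' @return Named list with `center`, `a`, `b`, `rotation`.
#' @export
default_gi_ellipse <- function() {
  list(center = c(tpsa = 71.051, wlogp = 2.292),
       a = 142.081 / 2, b = 8.740 / 2,
       rotation = -1.031325 * pi / 180)
}

#' Classify gastrointestinal absorption
#'
#' A molecule is classified `"high"` iff its (TPSA, WLOGP) point lies inside
#' or on the configured ellipse (closed-region convention: boundary points
#' are `"high"`).
#'
#' @param tpsa Topological polar surface area (A^2), vectorized.
#' @param wlogp Wildman-Crippen logP, vectorized.
#' @param ellipse Ellipse parameters, see [default_gi_ellipse()].
#' @return Character vector of `"high"` / `"low"`.
#' @export
gi_classify <- function(tpsa, wlogp, ellipse = default_gi_ellipse()) {
  np_assert_finite(tpsa, "tpsa")
  np_assert_finite(wlogp, "wlogp")
  if (ellipse$a <= 0 || ellipse$b <= 0) {
    np_stop("np_config_error", "ellipse semi-axes must be positive")
  }
  dx <- tpsa - ellipse$center[["tpsa"]]
  dy <- wlogp - ellipse$center[["wlogp"]]
  co <- cos(ellipse$rotation); si <- sin(ellipse$rotation)
  u <- (dx * co + dy * si) / ellipse$a
  v <- (-dx * si + dy * co) / ellipse$b
  ifelse(u^2 + v^2 <= 1 + 1e-9, "high", "low")
}

#' Drug-likeness report for a descriptor table
#'
#' Evaluates all five rules plus the GI classifier for every compound.
#'
#' @param descriptors Tibble with `cid` and all descriptor fields.
#' @param thresholds Rule thresholds, see [default_rule_thresholds()].
#' @param ellipse GI ellipse, see [default_gi_ellipse()].
#' @param violation_scope `"passed_only"` (default): `yes_violation_total`
#'   sums violations over rules that answered YES, the literal reading of
#'   screening condition (3). `"all_rules"`: sums over all five rules.
#' @return Tibble with per-rule `<rule>_passed` / `<rule>_violations`
#'   columns, `yes_count`, `yes_violation_total` and `gi_class`.
#' @export
druglikeness_report <- function(descriptors,
                                thresholds = default_rule_thresholds(),
                                ellipse = default_gi_ellipse(),
                                violation_scope = c("passed_only", "all_rules")) {
  violation_scope <- match.arg(violation_scope)
  d <- as_tibble(descriptors)
  out <- tibble(cid = d$cid)
  viol <- passed <- matrix(0L, nrow(d), length(adme_rules),
                           dimnames = list(NULL, adme_rules))
  for (r in adme_rules) {
    v <- rule_violations(r, d, thresholds)
    viol[, r] <- v
    passed[, r] <- as.integer(v <= thresholds[[r]]$max_violations)
    out[[paste0(r, "_passed")]] <- passed[, r] == 1L
    out[[paste0(r, "_violations")]] <- v
  }
  out$yes_count <- as.integer(rowSums(passed))
  out$yes_violation_total <- if (violation_scope == "passed_only") {
    as.integer(rowSums(viol * passed))
  } else {
    as.integer(rowSums(viol))
  }
  out$gi_class <- gi_classify(d$tpsa, d$wlogp, ellipse)
  out
}

#' Screen compounds with superior properties
#'
#' Retains compounds meeting all three screening conditions: high GI
#' absorption, 4 or 5 YES drug-likeness rules, and zero violations within
#' the YES rules. Output preserves input order.
#'
#' @param report Tibble from [druglikeness_report()].
#' @param min_yes Minimum number of YES rules (default 4).
#' @return Vector of retained `cid`s.
#' @export
screen_superior <- function(report, min_yes = 4L) {
  keep <- report$gi_class == "high" &
    report$yes_count >= min_yes &
    report$yes_violation_total == 0L
  report$cid[keep]
}
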