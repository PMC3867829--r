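# Neurologic deficit score (NDS) for rodent global cerebral ischemia:
# seven categories, total 0 (no deficit) to 500 (brain death).

# Allowed per-category values.
.nds_levels <- list(
  consciousness = c(0, 50, 100),
  respiration   = c(0, 50, 100),
  cornea_reflex = c(0, 20, 40),
  cranial_reflex = c(0, 15, 30),
  auditory_reflex = c(0, 15, 30),
  motor_sensory = c(0, 50, 100),
  behavior      = c(0, 50, 100))

#' NDS category definitions
#'
#' @return A named list: allowed score values per category. Scores grade
#'   deficit severity (0 = intact response, maximum = absent), and the seven
#'   category maxima sum to 500 (brain death).
#' @export
nds_categories <- function() .nds_levels

#' Validate and total a neurologic deficit score record
#'
#' @param scores Named numeric vector or list with one value per NDS category
#'   (`consciousness`, `respiration`, `cornea_reflex`, `cranial_reflex`,
#'   `auditory_reflex`, `motor_sensory`, `behavior`), each taken from its
#'   allowed set.
#' @return The total score, an integer in `[0, 500]`.
#' @examples
#' nds_total(c(consciousness = 50, respiration = 0, cornea_reflex = 20,
#'             cranial_reflex = 0, auditory_reflex = 15,
#'             motor_sensory = 50, behavior = 50))
#' @export
nds_total <- function(scores) {
  scores <- unlist(scores)
  cats <- names(.nds_levels)
  if (is.null(names(scores))) {
    if (length(scores) != length(cats))
      stop("need one score per NDS category", call. = FALSE)
    names(scores) <- cats
  }
  missing <- setdiff(cats, names(scores))
  if (length(missing))
    stop("missing NDS categories: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (cat in cats) {
    v <- scores[[cat]]
    if (!v %in% .nds_levels[[cat]])
      stop(sprintf("invalid value %s for NDS category '%s' (allowed: %s)",
                   format(v), cat,
                   paste(.nds_levels[[cat]], collapse = ", ")),
           call. = FALSE)
  }
  sum(scores[cats])
}
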