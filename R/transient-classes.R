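# The fourteen-class transient taxonomy and its primary groupings.

.ATP_SECONDARY <- c("1a", "1b", "1c", "2a", "2b", "2c", "3a", "3b", "3c")
.WOUND_EXTRA   <- c("W1", "W2", "W3", "W4", "W5")
.ALL_SECONDARY <- c(.ATP_SECONDARY, .WOUND_EXTRA)

.CLASS_DESCRIPTION <- c(
  "1a" = "non-responding",
  "1b" = "slowly rising",
  "1c" = "slowly rising-peak-baseline",
  "2a" = "peak-plateau",
  "2b" = "peak-plateau-peak-plateau",
  "2c" = "peak-baseline-spiking-plateau",
  "3a" = "peak-baseline-peak-baseline",
  "3b" = "peak-baseline-spiking",
  "3c" = "peak-plateau-spiking",
  "W1" = "slowly rising-peak-plateau",
  "W2" = "peak-plateau-baseline",
  "W3" = "peak-plateau-plateau",
  "W4" = "peak-baseline-peak-plateau",
  "W5" = "peak-baseline-plateau")

# Spiking/bursting classes were observed only under sustained agonist
# perfusion, never after wounding.
.SPIKING_CLASSES <- c("2c", "3b", "3c")

#' Primary group of a secondary transient class
#'
#' Under the agonist (ATP) protocol the three primary groups are
#' `1` (slow or absent response), `2` (rapid peak, then plateau) and
#' `3` (rapid peak, then spiking). Under the wound protocol the primary
#' grouping reflects the early response (first 10 min post-wound):
#' `slow/absent`, `peak-plateau` or `peak-baseline`.
#'
#' @param secondary character vector of secondary class labels (`"1a"` ...
#'   `"3c"`, `"W1"` ... `"W5"`).
#' @param protocol `"ATP"` or `"wound"`.
#' @return character vector of primary group labels.
#' @examples
#' primaryClass(c("2a", "3b"), "ATP")
#' primaryClass(c("W4", "2a"), "wound")
#' @export
primaryClass <- function(secondary, protocol = c("ATP", "wound")) {
  protocol <- match.arg(protocol)
  bad <- setdiff(secondary, .ALL_SECONDARY)
  if (length(bad))
    stop("unknown secondary class label(s): ", paste(bad, collapse = ", "))
  if (protocol == "ATP") {
    if (any(secondary %in% .WOUND_EXTRA))
      stop("W-classes are only defined under the wound protocol")
    substr(secondary, 1L, 1L)
  } else {
    map <- c("1a" = "slow/absent", "1b" = "slow/absent", "1c" = "slow/absent",
             "W1" = "slow/absent",
             "2a" = "peak-plateau", "2b" = "peak-plateau",
             "W2" = "peak-plateau", "W3" = "peak-plateau",
             "2c" = "peak-baseline", "3a" = "peak-baseline",
             "3b" = "peak-baseline", "3c" = "peak-baseline",
             "W4" = "peak-baseline", "W5" = "peak-baseline")
    unname(map[secondary])
  }
}

#' The transient-class taxonomy
#'
#' @param protocol `"ATP"` (nine classes) or `"wound"` (the nine classes that
#'   occur after wounding: the four shared with the agonist experiment plus
#'   the five wound-specific classes).
#' @return data.frame with columns `secondary`, `primary`, `description`.
#' @examples
#' transientClasses("ATP")
#' @export
transientClasses <- function(protocol = c("ATP", "wound")) {
  protocol <- match.arg(protocol)
  sec <- if (protocol == "ATP") .ATP_SECONDARY
         else c("1a", "1b", "2a", "2b", .WOUND_EXTRA)
  data.frame(secondary = sec,
             primary = primaryClass(sec, protocol),
             description = unname(.CLASS_DESCRIPTION[sec]),
             stringsAsFactors = FALSE)
}

#' Observed agonist-protocol class mixture
#'
#' Per-replicate secondary-class counts observed under 25 uM ATP perfusion
#' (replicates n = 114, 117, 126), and the pooled mixture used as the default
#' generating distribution for synthetic agonist populations.
#'
#' @param pooled if `TRUE` (default) return the pooled class proportions as a
#'   named numeric vector summing to 1; otherwise the 9 x 3 count matrix.
#' @return named numeric vector of proportions, or an integer matrix with one
#'   row per secondary class and one column per replicate.
#' @examples
#' atpClassMixture()
#' colSums(atpClassMixture(pooled = FALSE))
#' @export
atpClassMixture <- function(pooled = TRUE) {
  counts <- matrix(c(
    12, 11,  8,   # 1a
     8, 13, 11,   # 1b
     4,  5,  1,   # 1c
    27, 24, 31,   # 2a
     5,  3,  6,   # 2b
     7, 10,  3,   # 2c
     6,  3,  4,   # 3a
    24, 29, 33,   # 3b
    21, 19, 29),  # 3c
    nrow = 9, byrow = TRUE,
    dimnames = list(.ATP_SECONDARY, paste0("rep", 1:3)))
  if (!pooled) return(counts)
  p <- rowSums(counts) / sum(counts)
  p / sum(p)
}

#' Wound-protocol class mixtures by wound proximity
#'
#' Secondary-class mixtures for cells proximal (< 100 um) and distal
#' (>= 100 um) to the wound edge. The primary-group weights (proximal:
#' slow/absent 10%, peak-plateau 64%, peak-baseline 26%; distal: 40%, 1%,
#' 59%) reflect the observed concentration of peak-plateau responses at the
#' wound edge; the split across secondary classes within each group is a
#' modelling convention (see the methods vignette).
#'
#' @param region `"proximal"` or `"distal"`.
#' @return named numeric vector of class proportions summing to 1.
#' @examples
#' woundClassMixture("proximal")
#' @export
woundClassMixture <- function(region = c("proximal", "distal")) {
  region <- match.arg(region)
  p <- if (region == "proximal") {
    c("1a" = 0.04, "1b" = 0.04, "W1" = 0.02,
      "2a" = 0.40, "2b" = 0.06, "W2" = 0.09, "W3" = 0.09,
      "W4" = 0.08, "W5" = 0.18)
  } else {
    c("1a" = 0.18, "1b" = 0.16, "W1" = 0.06,
      "2a" = 0.01,
      "W4" = 0.12, "W5" = 0.47)
  }
  p / sum(p)
}
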