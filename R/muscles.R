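# Muscle and group vocabularies shared by every module.

.MUSCLES <- c("BICEPS", "FDI", "APB", "ADM", "QUADRICEPS",
              "TIBIALIS_ANTERIOR", "AHB", "EDB")

# Only these four muscles are imaged in the maximally contracted state.
.CONTRACTED_MUSCLES <- c("BICEPS", "APB", "QUADRICEPS", "TIBIALIS_ANTERIOR")

# Proximal subset used by the restricted fasciculation rule.
.PROXIMAL_MUSCLES <- c("BICEPS", "QUADRICEPS")

.GROUPS <- c("CONTROL", "MYO", "PNP", "ALS", "SMA")
.SEXES  <- c("F", "M")
.SIDES  <- c("RIGHT", "LEFT")
.STATES <- c("RELAXED", "CONTRACTED")

# column suffix used in cohort files for each muscle
.MUSCLE_COL <- c(BICEPS = "biceps", FDI = "fdi", APB = "apb", ADM = "adm",
                 QUADRICEPS = "quad", TIBIALIS_ANTERIOR = "ta",
                 AHB = "ahb", EDB = "edb")

.MRC_MOVEMENTS <- c("shoulder_abd", "elbow_flex", "elbow_ext",
                    "finger_abd", "finger_ext", "hip_flex", "knee_ext",
                    "dorsiflex", "plantarflex", "bigtoe_ext")

#' Studied muscles
#'
#' The eight limb muscles assessed sonographically in the relaxed state:
#' biceps brachii (with underlying brachialis), first dorsal interosseous
#' (FDI), abductor pollicis brevis (APB), abductor digiti minimi (ADM),
#' quadriceps, tibialis anterior, abductor hallucis brevis (AHB), and
#' extensor digitorum brevis (EDB).
#'
#' @return Character vector of the eight muscle identifiers.
#' @export
#' @examples
#' muscles()
muscles <- function() .MUSCLES

#' Contracted-capable muscles
#'
#' The four muscles additionally imaged in the maximally contracted state.
#'
#' @return Character vector of four muscle identifiers.
#' @export
contracted_muscles <- function() .CONTRACTED_MUSCLES

#' Proximal muscles used by the restricted fasciculation rule
#'
#' @return Character vector: biceps and quadriceps.
#' @export
proximal_muscles <- function() .PROXIMAL_MUSCLES

#' Diagnosis groups
#'
#' @return Character vector: CONTROL, MYO (myopathy), PNP (polyneuropathy),
#'   ALS (amyotrophic lateral sclerosis), SMA (spinal muscular atrophy).
#' @export
diagnosis_groups <- function() .GROUPS

#' Tested MRC movements
#'
#' The ten movements graded on the Medical Research Council 0-5 scale
#' (plus/minus grades stored as decimals, e.g. 4.5).
#'
#' @return Character vector of movement identifiers (column suffixes).
#' @export
mrc_movements <- function() .MRC_MOVEMENTS

# thickness column name for a muscle/state, e.g. "rel_biceps", "con_quad"
thick_col <- function(muscle, state) {
  prefix <- ifelse(state == "RELAXED", "rel", "con")
  paste0(prefix, "_", .MUSCLE_COL[muscle])
}

fasc_col <- function(muscle) paste0("fasc_", .MUSCLE_COL[muscle])
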