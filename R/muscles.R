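#' @importFrom stats rnorm sd coef lm approx
#' @importFrom utils read.csv write.csv
NULL

MUSCLE_NAMES <- c("FCR", "FCU", "ECRL", "ECRB", "ECU", "APL")
SPECIFIC_TENSION <- 25  # N/cm^2, constant

#' Read a muscle parameter table
#'
#' Reads a delimited text file with columns `name, pcsa_cm2, r_fe_mm,
#' r_rud_mm, f_max_N`.  A blank `f_max_N` is filled in as
#' 25 N/cm^2 (specific tension) times the PCSA.  Moment arms are signed
#' following ISB conventions: flexion positive, ulnar deviation positive.
#'
#' @param path Path to a CSV file.
#' @return A validated `data.frame` of class `muscle_table`.
#' @seealso [wrist_muscles()] for the bundled default table.
#' @export
read_muscle_table <- function(path) {
  if (!file.exists(path)) stop("muscle table not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "pcsa_cm2", "r_fe_mm", "r_rud_mm", "f_max_N")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    stop("muscle table is missing column(s): ", paste(missing, collapse = ", "))
  }
  m$f_max_N <- suppressWarnings(as.numeric(m$f_max_N))
  blank <- is.na(m$f_max_N)
  m$f_max_N[blank] <- SPECIFIC_TENSION * m$pcsa_cm2[blank]
  validate_muscle_table(m)
}

#' Default wrist muscle table
#'
#' The six primary wrist movers: flexor carpi radialis (FCR), flexor
#' carpi ulnaris (FCU), extensor carpi radialis longus (ECRL) and brevis
#' (ECRB), extensor carpi ulnaris (ECU) and abductor pollicis longus
#' (APL).  PCSAs (cm^2) and signed moment arms (mm) about the
#' flexion-extension (FE) and radioulnar-deviation (RUD) axes are
#' literature-plausible magnitudes chosen for this virtual plant;
#' maximum forces are specific tension (25 N/cm^2) times PCSA.
#'
#' @return A `muscle_table` data.frame with one row per muscle.
#' @export
wrist_muscles <- function() {
  path <- system.file("extdata", "muscles_default.csv", package = "wristsim")
  if (path == "") {
    # during development (package not installed) fall back to source tree
    path <- file.path("inst", "extdata", "muscles_default.csv")
  }
  read_muscle_table(path)
}

#' Validate a muscle table
#'
#' Checks positivity of PCSA and maximum force, the ISB sign convention
#' of the moment arms (flexors positive about FE, ulnar deviators
#' positive about RUD), and that the 6x2 moment-arm matrix has rank 2 so
#' both axes are actuatable.
#'
#' @param m A data.frame with the muscle-table columns.
#' @return `m`, classed as `muscle_table`, invisibly validated.
#' @export
validate_muscle_table <- function(m) {
  stopifnot(is.data.frame(m))
  if (!setequal(m$name, MUSCLE_NAMES) || nrow(m) != 6L) {
    stop("muscle table must contain exactly the six muscles ",
         paste(MUSCLE_NAMES, collapse = ", "))
  }
  m <- m[match(MUSCLE_NAMES, m$name), , drop = FALSE]
  rownames(m) <- m$name
  if (any(!is.finite(m$pcsa_cm2)) || any(m$pcsa_cm2 <= 0)) {
    stop("pcsa_cm2 must be finite and > 0")
  }
  if (any(!is.finite(m$f_max_N)) || any(m$f_max_N <= 0)) {
    stop("f_max_N must be finite and > 0")
  }
  flexors <- c("FCR", "FCU")
  extensors <- c("ECRL", "ECRB", "ECU", "APL")
  ulnar <- c("FCU", "ECU")
  radial <- c("FCR", "ECRL", "APL")
  if (any(m[flexors, "r_fe_mm"] <= 0)) {
    stop("r_fe_mm must be > 0 for flexors (FCR, FCU)")
  }
  if (any(m[extensors, "r_fe_mm"] >= 0)) {
    stop("r_fe_mm must be < 0 for extensors (ECRL, ECRB, ECU, APL)")
  }
  if (any(m[ulnar, "r_rud_mm"] <= 0)) {
    stop("r_rud_mm must be > 0 for ulnar deviators (FCU, ECU)")
  }
  if (any(m[radial, "r_rud_mm"] >= 0)) {
    stop("r_rud_mm must be < 0 for radial deviators (FCR, ECRL, APL)")
  }
  R <- moment_arm_matrix(m)
  if (qr(R)$rank < 2L) stop("moment-arm matrix must have rank 2")
  class(m) <- c("muscle_table", "data.frame")
  m
}

#' Moment-arm matrix of a muscle table
#'
#' @param m A `muscle_table`.
#' @return A 6x2 numeric matrix (mm), rows named by muscle, columns
#'   `fe` and `rud`.
#' @export
moment_arm_matrix <- function(m) {
  R <- cbind(fe = m$r_fe_mm, rud = m$r_rud_mm)
  rownames(R) <- m$name
  R
}
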