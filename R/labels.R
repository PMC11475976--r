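.icbhi_vocabulary <- c("URTI", "COPD", "Bronchiectasis", "Pneumonia",
                       "Bronchiolitis", "Asthma", "LRTI", "Healthy")
.chronic <- c("COPD", "Asthma", "Bronchiectasis")
.non_chronic <- c("Pneumonia", "URTI", "Bronchiolitis", "LRTI")

#' Map respiratory diagnoses to the two classification cases
#'
#' Case 1 is the binary healthy/diseased scheme; Case 2 groups diseases into
#' chronic (COPD, asthma, bronchiectasis) versus non-chronic (pneumonia,
#' URTI, bronchiolitis, LRTI) alongside healthy. Diagnoses outside the
#' recognized vocabulary — including Cystic Fibrosis, which fits neither
#' group definition cleanly — are rejected with an error naming the
#' offending string rather than silently assigned.
#'
#' @param diagnoses character vector of diagnosis strings (case-sensitive).
#' @param case `1` (binary) or `2` (three-class).
#' @return Factor of class labels: levels `healthy`/`diseased` (Case 1) or
#'   `healthy`/`chronic`/`non_chronic` (Case 2).
#' @export
#' @examples
#' map_diagnosis_to_case(c("COPD", "Healthy", "URTI"), case = 2)
map_diagnosis_to_case <- function(diagnoses, case = 1) {
  diagnoses <- as.character(diagnoses)
  if (!case %in% c(1, 2)) stop("case: must be 1 or 2")
  unknown <- setdiff(unique(diagnoses), .icbhi_vocabulary)
  if (length(unknown) > 0) {
    stop("unmapped diagnosis: ", paste(unknown, collapse = ", "))
  }
  if (case == 1) {
    factor(ifelse(diagnoses == "Healthy", "healthy", "diseased"),
           levels = c("healthy", "diseased"))
  } else {
    out <- ifelse(diagnoses == "Healthy", "healthy",
                  ifelse(diagnoses %in% .chronic, "chronic", "non_chronic"))
    factor(out, levels = c("healthy", "chronic", "non_chronic"))
  }
}
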