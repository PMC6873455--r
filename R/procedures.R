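#' Define an index procedure
#'
#' A procedure definition names the procedure-code set that identifies an
#' index admission and the rules that scope its exclusions and case-mix
#' covariates: a trauma diagnosis-code set (hip and knee replacement
#' exclude trauma cases), a multi-level fusion rule (spinal fusion
#' excludes concomitant fusion at a second level), a cancer flag code set
#' (colectomy distinguishes cancer from non-cancer management), whether
#' only elective admissions qualify, and whether DRG weight / admission
#' acuity enter the case-mix model.
#'
#' Code sets are configuration inputs; the codes shipped in
#' [default_procedures()] are illustrative placeholders, not clinical
#' code lists.
#'
#' @param name procedure label, e.g. "PHR".
#' @param index_code_set non-empty character vector of procedure codes
#'   that identify an index admission.
#' @param trauma_exclusion_codes diagnosis codes that mark a trauma case
#'   (may be empty).
#' @param multilevel_fusion_rule apply the multi-level fusion exclusion
#'   (spinal fusion only).
#' @param fusion_level_codes procedure codes denoting distinct fusion
#'   levels; two or more on one index claim triggers the exclusion.
#' @param cancer_flag_codes diagnosis codes marking cancer management
#'   (colectomy only).
#' @param elective_only if `TRUE`, emergent index admissions are
#'   excluded; if `FALSE`, emergent status enters case mix as acuity.
#' @param use_drg_weight include DRG relative weight as a resource-use
#'   intensity covariate.
#' @return a `bv_procedure` list.
#' @export
procedure_definition <- function(name,
                                 index_code_set,
                                 trauma_exclusion_codes = character(),
                                 multilevel_fusion_rule = FALSE,
                                 fusion_level_codes = character(),
                                 cancer_flag_codes = character(),
                                 elective_only = TRUE,
                                 use_drg_weight = FALSE) {
  if (length(index_code_set) == 0)
    bv_abort(sprintf("procedure '%s': index_code_set must be non-empty", name),
             "bundlevar_config_error")
  if (multilevel_fusion_rule && length(fusion_level_codes) < 2)
    bv_abort(sprintf(
      "procedure '%s': multilevel_fusion_rule needs >= 2 fusion_level_codes",
      name), "bundlevar_config_error")
  structure(list(
    name = name,
    index_code_set = as.character(index_code_set),
    trauma_exclusion_codes = as.character(trauma_exclusion_codes),
    multilevel_fusion_rule = isTRUE(multilevel_fusion_rule),
    fusion_level_codes = as.character(fusion_level_codes),
    cancer_flag_codes = as.character(cancer_flag_codes),
    elective_only = isTRUE(elective_only),
    use_drg_weight = isTRUE(use_drg_weight)
  ), class = "bv_procedure")
}

#' Default procedure definitions for the five study procedures
#'
#' Primary hip replacement (PHR), primary knee replacement (PKR),
#' coronary artery bypass grafting (CABG), lumbar spinal fusion (LSF)
#' and colectomy, with illustrative code sets. CABG and colectomy are
#' not restricted to elective admissions; emergent status enters their
#' case-mix models as acuity, and DRG weight enters for CABG, LSF and
#' colectomy.
#'
#' @return named list of [procedure_definition()] objects.
#' @export
default_procedures <- function() {
  defs <- list(
    procedure_definition("PHR", index_code_set = "P8151",
                         trauma_exclusion_codes = c("D8080", "D8081")),
    procedure_definition("PKR", index_code_set = "P8154",
                         trauma_exclusion_codes = c("D8080", "D8081")),
    procedure_definition("CABG", index_code_set = c("P3610", "P3611", "P3612"),
                         elective_only = FALSE, use_drg_weight = TRUE),
    procedure_definition("LSF", index_code_set = c("P8106", "P8107", "P8108"),
                         multilevel_fusion_rule = TRUE,
                         fusion_level_codes = c("P8106", "P8107", "P8108"),
                         use_drg_weight = TRUE),
    procedure_definition("colectomy", index_code_set = c("P1731", "P1735"),
                         cancer_flag_codes = c("D1530", "D1539"),
                         elective_only = FALSE, use_drg_weight = TRUE)
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Read procedure definitions from a YAML config file
#'
#' The file holds a list of procedure entries with the fields of
#' [procedure_definition()].
#'
#' @param path YAML file path.
#' @return named list of `bv_procedure` objects.
#' @export
read_procedures <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- lapply(raw, function(p) {
    do.call(procedure_definition, c(
      list(name = p$name, index_code_set = p$index_code_set),
      p[setdiff(names(p), c("name", "index_code_set"))]
    ))
  })
  stats::setNames(defs, vapply(defs, `[[`, "", "name"))
}

#' Write procedure definitions to a YAML config file
#'
#' @param procedures named list of `bv_procedure` objects.
#' @param path output YAML file path.
#' @return `path`, invisibly.
#' @export
write_procedures <- function(procedures, path) {
  yaml::write_yaml(lapply(unname(procedures), unclass), path)
  invisible(path)
}
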