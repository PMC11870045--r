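#' Pharmacological condition definitions
#'
#' A drug condition is a named, invertible transformation of a
#' [neuron_spec()], emulating bath application of the study drugs:
#' \describe{
#'   \item{control}{identity.}
#'   \item{baclofen}{GABAb agonist: adds a GIRK conductance (`g_GIRK`) and
#'     multiplies the BK conductance by a suppression factor (default 0.2),
#'     the mechanistic stand-in for indirect BK inhibition.}
#'   \item{paxilline}{BK blocker: `g_BK` set to 0.}
#'   \item{picrotoxin}{GABAa blocker: `g_tonic_inh` set to 0.}
#'   \item{apv_dnqx}{glutamate-receptor blockers: background synaptic drive
#'     `I_bg` set to 0.}
#' }
#' Conditions compose: `drug_condition(c("picrotoxin", "paxilline",
#' "baclofen"))` applies the effects in order. Applying a condition with
#' [apply_condition()] and reverting with [revert_condition()] restores the
#' specification exactly.
#'
#' @param name character vector of one or more condition names.
#' @param girk_add GIRK conductance added by baclofen (nS).
#' @param bk_suppression multiplicative BK suppression under baclofen.
#' @return an object of class `drug_condition`.
#' @export
drug_condition <- function(name = "control", girk_add = 0.8,
                           bk_suppression = 0.2) {
  known <- c("control", "baclofen", "paxilline", "picrotoxin", "apv_dnqx")
  if (!all(name %in% known))
    ephys_error(paste0("unknown condition: ",
                       paste(setdiff(name, known), collapse = ", ")),
                "condition_error")
  structure(list(name = name, girk_add = girk_add,
                 bk_suppression = bk_suppression),
            class = "drug_condition")
}

#' @export
print.drug_condition <- function(x, ...) {
  cat("<drug_condition>", paste(x$name, collapse = " + "), "\n")
  invisible(x)
}

#' Apply / revert a drug condition
#'
#' @param spec a [neuron_spec()].
#' @param condition a [drug_condition()] (a character vector is promoted).
#' @return the modified `neuron_spec`; the original values of the touched
#'   fields are kept in the attribute `"pre_condition"` so that
#'   [revert_condition()] restores the input exactly.
#' @export
apply_condition <- function(spec, condition) {
  if (is.character(condition)) condition <- drug_condition(condition)
  stopifnot(inherits(spec, "neuron_spec"),
            inherits(condition, "drug_condition"))
  touched <- list(g_GIRK = spec$g_GIRK, g_BK = spec$g_BK,
                  g_tonic_inh = spec$g_tonic_inh, I_bg = spec$I_bg)
  out <- spec
  for (nm in condition$name) {
    out <- switch(nm,
      control = out,
      baclofen = {
        out$g_GIRK <- out$g_GIRK + condition$girk_add
        out$g_BK <- out$g_BK * condition$bk_suppression
        out
      },
      paxilline = { out$g_BK <- 0; out },
      picrotoxin = { out$g_tonic_inh <- 0; out },
      apv_dnqx = { out$I_bg <- 0; out })
  }
  attr(out, "pre_condition") <- touched
  attr(out, "condition") <- paste(condition$name, collapse = "+")
  out
}

#' @rdname apply_condition
#' @export
revert_condition <- function(spec) {
  pre <- attr(spec, "pre_condition")
  if (is.null(pre)) return(spec)
  for (nm in names(pre)) spec[[nm]] <- pre[[nm]]
  attr(spec, "pre_condition") <- NULL
  attr(spec, "condition") <- NULL
  spec
}
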