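#' Packaged demo pair of sensitive/resistant logic models
#'
#' A small, fully synthetic stand-in for a genotype pair whose resistant
#' member escapes receptor inhibition through a stress-kinase survival
#' axis. Both models share the receptor layer (FLT3 constitutive, IGF1R,
#' TNFR) and the proliferative arm FLT3 -> PI3K -> AKT -> RPS6; the
#' pro-apoptotic endpoint BAD is released by AKT inactivation alone in the
#' sensitive model, but in the resistant model BAD additionally requires
#' JNK (driven by TNFR) to be inactive — so FLT3 inhibition alone cannot
#' induce apoptosis there, and the JNK knockout is the unique rescue among
#' the default screen targets.
#'
#' @return list with `sensitive` and `resistant` (logic models),
#'   `regulators` (a `regulator_table`: BAD apoptosis activator, RPS6
#'   proliferation activator), and `receptors`.
#' @export
demo_model_pair <- function() {
  nodes <- data.frame(
    name = c("FLT3", "IGF1R", "TNFR", "PI3K", "AKT", "JNK", "ERK",
             "RPS6", "BAD"),
    category = "protein",
    is_measured = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    is_targeted = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  common <- data.frame(
    source = c("FLT3", "IGF1R", "TNFR", "PI3K", "AKT"),
    target = c("PI3K", "ERK", "JNK", "AKT", "RPS6"),
    sign = 1L, stringsAsFactors = FALSE)
  sens_net <- causal_network(
    edges = rbind(common, data.frame(source = "AKT", target = "BAD",
                                     sign = -1L, stringsAsFactors = FALSE)),
    nodes = nodes)
  res_net <- causal_network(
    edges = rbind(common,
                  data.frame(source = c("AKT", "JNK"), target = "BAD",
                             sign = -1L, stringsAsFactors = FALSE)),
    nodes = nodes)
  sens_scaffold <- expand(sens_net, max_gate_inputs = 2)
  res_scaffold <- expand(res_net, max_gate_inputs = 2)
  # sensitive: all (single-regulator) gates; resistant: BAD uses only the
  # two-input AND !AKT & !JNK
  sens_sel <- rep(1L, length(sens_scaffold$gates))
  res_sel <- vapply(res_scaffold$gates, function(g) {
    if (g$output != "BAD") return(1L)
    as.integer(length(g$inputs) == 2)
  }, integer(1))
  regulators <- data.frame(
    node = c("BAD", "RPS6"),
    phenotype = c("apoptosis", "proliferation"),
    effect = c(1L, 1L), stringsAsFactors = FALSE)
  class(regulators) <- c("regulator_table", "data.frame")
  list(sensitive = logic_model(sens_scaffold, sens_sel),
       resistant = logic_model(res_scaffold, res_sel),
       regulators = regulators,
       receptors = c("FLT3", "IGF1R", "TNFR"))
}
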