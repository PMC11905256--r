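# Experiment presets mirroring the component-ablation grid: each preset
# toggles the GLF bottleneck, the scale-aware (SAD) encoder blocks, and the
# mean-teacher consistency branch (SE-MT). Presets without SE-MT train
# jointly on SL + TL (the supervised domain-adaptation setting); the
# "supervised" preset is the target-only reference trained on TL alone.

#' Experiment preset
#'
#' @param name one of `"baseline"` (DSBN UNet, joint SL+TL), `"comb1"`
#'   (SE-MT only), `"comb2"` (GLF + SE-MT), `"comb3"` (SAD + SE-MT),
#'   `"comb4"` (GLF + SAD, joint SL+TL), `"full"` (GLF + SAD + SE-MT) or
#'   `"supervised"` (GLF + SAD network trained on TL only)
#' @return list with `use_glf`, `use_sad`, `use_semt`, `subsets`
#' @export
experiment_preset <- function(name = c("baseline", "comb1", "comb2", "comb3",
                                       "comb4", "full", "supervised")) {
  name <- match.arg(name)
  switch(name,
    baseline   = list(use_glf = FALSE, use_sad = FALSE, use_semt = FALSE,
                      subsets = c("SL", "TL")),
    comb1      = list(use_glf = FALSE, use_sad = FALSE, use_semt = TRUE,
                      subsets = c("SL", "TL")),
    comb2      = list(use_glf = TRUE, use_sad = FALSE, use_semt = TRUE,
                      subsets = c("SL", "TL")),
    comb3      = list(use_glf = FALSE, use_sad = TRUE, use_semt = TRUE,
                      subsets = c("SL", "TL")),
    comb4      = list(use_glf = TRUE, use_sad = TRUE, use_semt = FALSE,
                      subsets = c("SL", "TL")),
    full       = list(use_glf = TRUE, use_sad = TRUE, use_semt = TRUE,
                      subsets = c("SL", "TL")),
    supervised = list(use_glf = TRUE, use_sad = TRUE, use_semt = FALSE,
                      subsets = "TL"))
}

#' Train under a named preset
#'
#' Convenience wrapper: applies a preset's component flags to the network
#' and optimizer configuration and calls [train()].
#'
#' @param data a `split_dataset`
#' @param preset preset name, see [experiment_preset()]
#' @param steps training iterations
#' @param seed training seed
#' @param net_args,opt_args,loss_args extra overrides for
#'   [phantom_net_config()], [optim_config()], [loss_weights()]
#' @return the [train()] result
#' @export
train_preset <- function(data, preset = "full", steps = 100, seed = 1,
                         net_args = list(), opt_args = list(),
                         loss_args = list()) {
  p <- experiment_preset(preset)
  net_cfg <- do.call(phantom_net_config,
                     c(list(use_sad = p$use_sad, use_glf = p$use_glf),
                       net_args))
  opt_cfg <- do.call(optim_config,
                     c(list(steps = steps, use_semt = p$use_semt,
                            subsets = p$subsets), opt_args))
  if (identical(p$subsets, "TL")) {
    opt_cfg$batch_sl <- 0
    # matched total supervised batch width when only TL is available
    opt_cfg$batch_tl <- max(opt_cfg$batch_tl, 2)
  }
  w <- do.call(loss_weights, loss_args)
  train(data, net_cfg, w, opt_cfg, seed = seed)
}
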