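#!/usr/bin/env Rscript
# Step 1 -- Simulate the experimental scenes.
#
# Builds the two experiments' designs (black/white and brightness-matched
# red/blue backgrounds, 20 fish each, photographed at 0/1/10/60 min through
# a gamma-2.2 four-channel camera) and writes the scene plans, the
# ground-truth design table and a sample image stack so the raw artifacts
# can be inspected. Downstream steps re-render scenes in memory from the
# same seeds, so nothing below depends on these files.

suppressPackageStartupMessages(library(camochange))
dir.create("results/scenes", recursive = TRUE, showWarnings = FALSE)
seed <- 1

receiver <- receiver_model()
conditions <- lapply(1:2, experiment_conditions)
camera <- camera_model(noise_sd = conditions[[1]]$camera_noise_sd)

for (ex in 1:2) {
  bgs <- experiment_backgrounds(ex, camera, conditions[[ex]])
  plan <- scene_plan(ex, bgs,
                     n_fish_per_background = conditions[[ex]]$n_fish_per_background,
                     timepoints_min = conditions[[ex]]$timepoints_min,
                     seed = seed)
  write_plan_yaml(plan, sprintf("results/scenes/plan_exp%d.yaml", ex))
  traj <- default_trajectories(plan, receiver, conditions[[ex]])
  scene <- render_scene(plan, traj, camera, receiver$illuminant,
                        nrow = conditions[[ex]]$image_side,
                        ncol = conditions[[ex]]$image_side)
  gt <- scene$ground_truth[, c("stack", "fish_id", "background",
                               "time_min", "experiment")]
  gt$true_mean_reflectance <- vapply(scene$ground_truth$fish_spectrum,
                                     function(s) mean(s$reflectance),
                                     numeric(1))
  write.csv(gt, sprintf("results/scenes/ground_truth_exp%d.csv", ex),
            row.names = FALSE)
  write_stack_tiff(scene$stacks[[1]],
                   sprintf("results/scenes/sample_stack_exp%d.tif", ex))
  write_stack_masks(scene$stacks[[1]],
                    sprintf("results/scenes/sample_standard_mask_exp%d.png", ex),
                    sprintf("results/scenes/sample_fish_mask_exp%d.png", ex))
  cat(sprintf(
    "experiment %d: rendered %d stacks (%s backgrounds), %d x %d px\n",
    ex, length(scene$stacks), paste(names(bgs), collapse = "/"),
    conditions[[ex]]$image_side, conditions[[ex]]$image_side))
}
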