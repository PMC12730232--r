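#!/usr/bin/env Rscript
# Generate the synthetic ToF-SIMS experiment used by the downstream
# analyses and demonstrate the on-disk interchange format.
#
# The replicate-heavy statistics in later scripts simulate cell-area (ROI)
# spectra directly in memory; here we additionally write a small imaging
# experiment (reduced 100-320 Da axis, 16x16 px fields) as imzML/ibd with
# its ground-truth manifest, to show the full file-based route. Binary
# cubes go under scratch/ (they are reproducible from the seed); the
# manifest summary table lands in results/.

suppressPackageStartupMessages(library(simslipid))

seed <- 1L
out_dir <- "scratch/synthetic_experiment"
res_dir <- "results"
dir.create(res_dir, showWarnings = FALSE)

# small disk demo: a handful of low-mass ions so the continuous-mode
# cubes stay small
species <- data.frame(
  name = c("C5H15PNO4", "MG 12:0", "FA 12:0", "FA 16:0", "FA 18:0"),
  ions = c("+", "+H", "-H", "-H", "-H"),
  explicit_formula = "", stringsAsFactors = FALSE)
lib_small <- build_ion_library(species)
lib_small$rel_intensity <- c(100, 40, 30, 80, 60)
lib_small$tier <- "major"

cfg_small <- sim_config(
  nx = 16L, ny = 16L, n_cells = 2L, cell_axes = c(3, 2),
  lipidome = lib_small,
  incorporation = list("13C-palmitate" = list(
    label = "c13:1",
    targets = data.frame(name = "FA 16:0", f = 0.3))),
  axis = mass_axis(100, 320, 0.05), n_bg_bins = 60L,
  seed = seed)

manifest <- generate_experiment(cfg_small, out_dir,
                                arms = "13C-palmitate",
                                n_control_images = 2L,
                                n_treated_images = 1L)
man <- jsonlite::fromJSON(manifest)
cat(sprintf("wrote %d imzML cubes under %s (config %s)\n",
            length(man$files$file), out_dir, man$config_digest))

# the full-scale in-memory conditions used by scripts 03-05
cfg_full <- sim_config(seed = seed)
write_result_tsv(
  data.frame(name = cfg_full$lipidome$name,
             ion_form = cfg_full$lipidome$ion_form,
             mz = round(cfg_full$lipidome$mz, 4),
             polarity = cfg_full$lipidome$polarity,
             class = cfg_full$lipidome$class,
             rel_intensity = signif(cfg_full$lipidome$rel_intensity, 4),
             tier = cfg_full$lipidome$tier),
  file.path(res_dir, "lipidome.tsv"),
  params = list(seed = seed))
cat(sprintf("ground-truth lipidome: %d ions (%d per polarity) -> %s\n",
            nrow(cfg_full$lipidome), sum(cfg_full$lipidome$polarity == 1),
            file.path(res_dir, "lipidome.tsv")))
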