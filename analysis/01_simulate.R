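#!/usr/bin/env Rscript
# Simulate one co-located imaging experiment and write it to disk in the
# interchange formats the rest of the workflow consumes: a hyperspectral
# raw/dark/standard cube set (multi-page TIFF + wavelength headers), an
# optode RGB frame series (16-bit TIFFs + CSV manifest), a light-events
# table, a calibration series, and the generator's ground truth.

suppressPackageStartupMessages(library(farredo2))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(i <- which(args == "--seed"))) as.integer(args[i + 1]) else 42L

data_dir <- "results/data"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

message("Simulating co-located hyperspectral + optode experiment (seed ",
        seed, ")")
ex <- synth_colocated_experiment(seed = seed, noise_sigma = 2, snr = 50)

# hyperspectral cube set
write_spectral_cube(ex$scene$raw, file.path(data_dir, "sample_raw.tif"))
write_spectral_cube(ex$scene$dark, file.path(data_dir, "dark.tif"))
write_spectral_cube(ex$scene$standard, file.path(data_dir, "standard.tif"))

# optode frames + manifest + events
write_optode_frames(ex$optode$frames, file.path(data_dir, "frames"))
utils::write.csv(ex$optode$truth$params$events,
                 file.path(data_dir, "events.csv"), row.names = FALSE)

# calibration series: whole-field-of-view ROI means at 8 known O2 levels
cal <- synth_calibration_series(a = 0.8, b = 0.05, sigma = 0.001,
                                seed = seed + 1)
utils::write.csv(cal, file.path(data_dir, "calibration_pairs.csv"),
                 row.names = FALSE)

# ground truth for later comparison
write_scalar_image_csv(scalar_image(ex$scene$truth$chlf_map, "dip_depth"),
                       file.path(data_dir, "truth_chlf_map.csv"))
write_scalar_image_csv(scalar_image(ex$optode$truth$c_ss, "percent_airsat"),
                       file.path(data_dir, "truth_c_ss.csv"))
rd_tr <- ex$optode$truth$events[[1]]$bracket_umol
pn_tr <- ex$optode$truth$events[[2]]$bracket_umol
write_scalar_image_csv(scalar_image(rd_tr, "umol_O2_per_L_per_min"),
                       file.path(data_dir, "truth_rd.csv"))
write_scalar_image_csv(scalar_image(pn_tr, "umol_O2_per_L_per_min"),
                       file.path(data_dir, "truth_pn.csv"))

message("Scene: ", nrow(ex$centers), " chlorophyll f hotspots at rows ",
        paste(ex$centers$row, collapse = ", "), "; 2% reflectance noise; ",
        "optode SNR 50.")
message("Wrote ", data_dir, "/ (cubes, ", length(ex$optode$frames),
        " frames, calibration series, truth)")
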