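Package: bindecode
Title: Decoding Perception-Action Binding from Oscillatory EEG Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of event-file binding effects in
    Go/Nogo EEG experiments. Provides a synthetic multi-subject EEG
    generator with planted theta- and alpha-band condition effects, a
    preprocessing chain (IIR band-pass and notch filtering, resampling,
    average re-referencing, amplitude-based artifact rejection, baseline
    correction), Morlet wavelet time-frequency decomposition with band
    power extraction and peak-latency estimation, cluster-based
    permutation statistics (paired t and Wilcoxon element statistics over
    channel-time, time-time and voxel domains), LCMV beamformer source
    reconstruction on a regular voxel grid with atlas bookkeeping,
    multivariate pattern analysis (temporal decoding, temporal
    generalization, cross-frequency transfer, per-voxel spatial decoding)
    with linear support vector machines and AUC scoring, DBSCAN
    localization of peak-decoding voxels, and brain-behavior statistics
    including Wilcoxon signed-rank tests with Rosenthal effect sizes and
    backward-elimination multiple regression with collinearity and
    autocorrelation diagnostics. A pipeline orchestrator runs the full
    chain end to end with seed-reproducible stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
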