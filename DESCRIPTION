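Package: speechprime
Title: Sublexical Auditory Priming: Modulation-Filtered Speech Degradation
    and Event-Related fMRI Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how clear sublexical speech (pseudowords)
    primes the perception of degraded speech, and for analysing the
    accompanying BOLD responses. Implements modulation-power-spectrum
    degradation of audio (log-spectrogram, 2D Fourier transform, band
    masking, Griffin-Lim style spectrogram inversion), wideband-envelope
    similarity via a log-spaced filterbank and maximum lagged correlation,
    three-level whole-pseudoword repetition scoring, generators for
    synthetic pseudoword audio, gamma-jittered event schedules, simulated
    repetition responses and simulated BOLD volumes, and the event-related
    GLM analysis chain: HRF-convolved design matrices, voxelwise
    least-squares fits, F contrasts, conjunction-null maps, permutation
    cluster correction, repeated-measures ANOVAs and FDR-corrected
    post-hoc paired t-tests over auditory-cortex ROIs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    RNifti,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
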