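#!/usr/bin/env python
"""Independent scipy-based implementation of the 1/f + Gaussian-peaks
spectral parameterization algorithm, used once as a cross-check oracle.

Reads a long-format CSV (spectrum_id, freq, psd) and writes per-spectrum
fits (offset, exponent, n_peaks, cf1..) to stdout-specified CSV. The
published procedure: robust aperiodic fit (fit, clip below-line residuals
to zero, mask bins above a low residual percentile, refit), iterative
Gaussian peak extraction on the flattened spectrum with absolute and
relative (SD-based) height floors, joint bounded least-squares refit,
edge/proximity pruning, and a final aperiodic refit on the peak-removed
spectrum.

Usage: python specparam_oracle.py input.csv output.csv
"""
import sys

import numpy as np
import pandas as pd
from scipy.optimize import curve_fit

FREQ_RANGE = (0.5, 40.0)
WIDTH_LIMITS = (0.5, 12.0)  # full width; Gaussian SD limits are half
MAX_N_PEAKS = 3
MIN_PEAK_HEIGHT = 0.3
PEAK_THRESHOLD_SD = 2.0
AP_PERCENTILE = 0.025


def aperiodic(logf, offset, exponent):
    return offset - exponent * logf


def simple_ap_fit(logf, logp):
    popt, _ = curve_fit(aperiodic, logf, logp, p0=[logp[0], 1.0])
    return popt


def robust_ap_fit(logf, logp):
    popt = simple_ap_fit(logf, logp)
    flat = logp - aperiodic(logf, *popt)
    flat[flat < 0] = 0
    thresh = np.percentile(flat, AP_PERCENTILE)
    mask = flat <= thresh
    if mask.sum() < 3:
        mask[:] = True
    return simple_ap_fit(logf[mask], logp[mask])


def gauss_sum(freqs, *params):
    out = np.zeros_like(freqs)
    for i in range(0, len(params), 3):
        cf, h, sd = params[i:i + 3]
        out = out + h * np.exp(-((freqs - cf) ** 2) / (2 * sd ** 2))
    return out


def fit_one(freqs, psd):
    sel = (freqs >= FREQ_RANGE[0]) & (freqs <= FREQ_RANGE[1])
    f, p = freqs[sel], psd[sel]
    logf, logp = np.log10(f), np.log10(p)
    std_lim = (WIDTH_LIMITS[0] / 2, WIDTH_LIMITS[1] / 2)

    ap = robust_ap_fit(logf, logp)
    flat = logp - aperiodic(logf, *ap)

    guesses = []
    flat_iter = flat.copy()
    for _ in range(MAX_N_PEAKS):
        idx = int(np.argmax(flat_iter))
        h = flat_iter[idx]
        if h <= PEAK_THRESHOLD_SD * np.std(flat_iter, ddof=1):
            break
        if h <= MIN_PEAK_HEIGHT:
            break
        cf = f[idx]
        half = h / 2
        li = idx
        while li > 0 and flat_iter[li] > half:
            li -= 1
        ri = idx
        while ri < len(f) - 1 and flat_iter[ri] > half:
            ri += 1
        sides = []
        if flat_iter[li] <= half:
            sides.append(cf - f[li])
        if flat_iter[ri] <= half:
            sides.append(f[ri] - cf)
        if sides:
            sd0 = 2 * min(sides) / (2 * np.sqrt(2 * np.log(2)))
        else:
            sd0 = np.mean(std_lim)
        sd0 = float(np.clip(sd0, *std_lim))
        guesses.append((cf, h, sd0))
        flat_iter = flat_iter - h * np.exp(-((f - cf) ** 2) / (2 * sd0 ** 2))

    peaks = np.empty((0, 3))
    if guesses:
        g = np.array(guesses)
        p0 = g.ravel()
        lo = np.column_stack([np.maximum(g[:, 0] - 1.5 * g[:, 2], FREQ_RANGE[0]),
                              np.zeros(len(g)), np.full(len(g), std_lim[0])]).ravel()
        hi = np.column_stack([np.minimum(g[:, 0] + 1.5 * g[:, 2], FREQ_RANGE[1]),
                              np.full(len(g), np.inf), np.full(len(g), std_lim[1])]).ravel()
        try:
            popt, _ = curve_fit(gauss_sum, f, flat, p0=p0, bounds=(lo, hi),
                                maxfev=5000)
        except RuntimeError:
            popt = p0
        peaks = popt.reshape(-1, 3)
        keep = ((peaks[:, 0] - peaks[:, 2] >= FREQ_RANGE[0]) &
                (peaks[:, 0] + peaks[:, 2] <= FREQ_RANGE[1]))
        peaks = peaks[keep]
        if len(peaks) > 1:
            order = np.argsort(-peaks[:, 1])
            kept = []
            for j in order:
                if all(abs(peaks[j, 0] - peaks[k, 0]) >= PEAK_THRESHOLD_SD * peaks[k, 2]
                       for k in kept):
                    kept.append(j)
            peaks = peaks[sorted(kept)]

    ap = simple_ap_fit(logf, logp - gauss_sum(f, *peaks.ravel()))
    model = aperiodic(logf, *ap) + gauss_sum(f, *peaks.ravel())
    r2 = np.corrcoef(logp, model)[0, 1] ** 2
    cfs = sorted(peaks[:, 0])
    return {
        "offset": ap[0], "exponent": ap[1], "n_peaks": len(peaks), "r2": r2,
        "cf1": cfs[0] if len(cfs) > 0 else np.nan,
        "cf2": cfs[1] if len(cfs) > 1 else np.nan,
        "cf3": cfs[2] if len(cfs) > 2 else np.nan,
    }


def main(inp, out):
    df = pd.read_csv(inp)
    rows = []
    for sid, grp in df.groupby("spectrum_id"):
        grp = grp.sort_values("freq")
        res = fit_one(grp["freq"].to_numpy(), grp["psd"].to_numpy())
        res["spectrum_id"] = int(sid)
        rows.append(res)
    cols = ["spectrum_id", "offset", "exponent", "n_peaks", "r2", "cf1", "cf2", "cf3"]
    pd.DataFrame(rows)[cols].to_csv(out, index=False, float_format="%.6f")


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
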