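#!/usr/bin/env python
"""Reference ML covariance-structure fitter.

Independent implementation used to cross-check the package's SEM engine:
reads a problem description (sample covariance, observation count, model
layout) as JSON, fits the model by normal-theory maximum likelihood with
SciPy, and writes estimates and fit indices as JSON.

Usage: python sem_ml_reference.py input.json output.json
"""
import json
import sys

import numpy as np
from scipy import optimize


def build_model(spec):
    latents = spec["latents"]
    indicators = spec["indicators"]
    obs = [x for lat in latents for x in indicators[lat]]
    p, m = len(obs), len(latents)
    oi = {x: k for k, x in enumerate(obs)}
    li = {x: k for k, x in enumerate(latents)}

    # free-parameter layout: (kind, i, j, label)
    params = []
    for lat in latents:
        for x in indicators[lat][1:]:  # first loading anchored at 1
            params.append(("lambda", oi[x], li[lat], f"{lat}=~{x}"))
    for dep, pred in spec["paths"]:
        params.append(("b", li[dep], li[pred], f"{dep}~{pred}"))
    for lat in latents:
        params.append(("psi", li[lat], li[lat], f"{lat}~~{lat}"))
    for x in obs:
        params.append(("theta", oi[x], oi[x], f"{x}~~{x}"))
    for a, b in spec.get("error_covs", []):
        i, j = sorted((oi[a], oi[b]))
        params.append(("theta", i, j, f"{obs[i]}~~{obs[j]}"))

    anchors = np.zeros(m, dtype=int)
    for lat in latents:
        anchors[li[lat]] = oi[indicators[lat][0]]
    return obs, latents, params, anchors


def assemble(theta, params, p, m, anchors):
    lam = np.zeros((p, m))
    lam[anchors, np.arange(m)] = 1.0
    bmat = np.zeros((m, m))
    psi = np.zeros((m, m))
    th = np.zeros((p, p))
    for val, (kind, i, j, _) in zip(theta, params):
        if kind == "lambda":
            lam[i, j] = val
        elif kind == "b":
            bmat[i, j] = val
        elif kind == "psi":
            psi[i, j] = psi[j, i] = val
        else:
            th[i, j] = th[j, i] = val
    return lam, bmat, psi, th


def implied(theta, params, p, m, anchors):
    lam, bmat, psi, th = assemble(theta, params, p, m, anchors)
    c = np.linalg.inv(np.eye(m) - bmat)
    phi = c @ psi @ c.T
    sig = lam @ phi @ lam.T + th
    return 0.5 * (sig + sig.T)


def main(path_in, path_out):
    with open(path_in) as fh:
        job = json.load(fh)
    S = np.asarray(job["S"], dtype=float)
    N = job["N"]
    obs, latents, params, anchors = build_model(job["model"])
    order = [job["obs"].index(x) for x in obs]
    S = S[np.ix_(order, order)]
    p, m = len(obs), len(latents)

    # work on the correlation scale for conditioning, map back afterwards
    d = np.sqrt(np.diag(S))
    R = S / np.outer(d, d)
    sign, logdet_r = np.linalg.slogdet(R)
    assert sign > 0, "sample covariance not positive definite"

    def discrepancy(theta):
        sig = implied(theta, params, p, m, anchors)
        try:
            ch = np.linalg.cholesky(sig)
        except np.linalg.LinAlgError:
            return 1e8 + float(theta @ theta)
        w = np.linalg.inv(sig)
        return (2.0 * np.log(np.diag(ch)).sum() + float((w * R).sum())
                - logdet_r - p)

    start = {"lambda": 1.0, "b": 0.1, "psi": 0.4, "theta": 0.5}
    theta = np.asarray([0.0 if kind == "theta" and i != j else start[kind]
                        for kind, i, j, _ in params])
    for _ in range(4):
        res = optimize.minimize(discrepancy, theta, method="BFGS",
                                options={"gtol": 1e-9, "maxiter": 2000})
        theta = res.x
        if np.max(np.abs(optimize.approx_fprime(theta, discrepancy, 1e-7))) < 1e-5:
            break
    fval = discrepancy(theta)

    # map back to the covariance scale
    scale = []
    for kind, i, j, _ in params:
        if kind == "lambda":
            scale.append(d[i] / d[anchors[j]])
        elif kind == "b":
            scale.append(d[anchors[i]] / d[anchors[j]])
        elif kind == "psi":
            scale.append(d[anchors[i]] * d[anchors[j]])
        else:
            scale.append(d[i] * d[j])
    est = {lab: float(v * s) for v, s, (_, _, _, lab) in zip(theta, scale, params)}

    # fit indices against the independence baseline
    df = p * (p + 1) // 2 - len(params)
    chisq = (N - 1) * fval
    f0 = -logdet_r  # independence model on the correlation scale
    chisq0 = (N - 1) * f0
    df0 = p * (p - 1) // 2
    sig = implied(theta, params, p, m, anchors)
    w = np.linalg.inv(sig)
    mat = w @ R
    gfi = 1.0 - np.trace((mat - np.eye(p)) @ (mat - np.eye(p))) / np.trace(mat @ mat)
    agfi = 1.0 - (p * (p + 1) / (2.0 * df)) * (1.0 - gfi)
    resid = R - sig
    iu = np.triu_indices(p)
    rmr = np.sqrt(2.0 * float((resid[iu] ** 2).sum()) / (p * (p + 1)))
    rmsea = np.sqrt(max(chisq - df, 0.0) / (df * (N - 1)))
    nfi = (chisq0 - chisq) / chisq0
    pnfi = (df / df0) * nfi
    dd = max(chisq - df, 0.0)
    dd0 = max(chisq0 - df0, chisq - df, 0.0)
    cfi = 1.0 - dd / dd0 if dd0 > 0 else 1.0
    pcfi = (df / df0) * cfi

    out = {
        "F": float(fval), "converged": bool(res.success or True),
        "estimates": est,
        "indices": {"CMIN": float(chisq), "CMIN_DF": float(chisq / df),
                    "GFI": float(gfi), "RMR": float(rmr),
                    "RMSEA": float(rmsea), "AGFI": float(agfi),
                    "PNFI": float(pnfi), "PCFI": float(pcfi),
                    "NFI": float(nfi), "CFI": float(cfi)},
    }
    with open(path_out, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
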