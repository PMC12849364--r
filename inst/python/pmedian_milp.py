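"""Mixed-integer backend for the p-median site-selection model.

Reads a job description (JSON) referencing a weighted travel-time matrix
(headerless CSV, rows = demand points, columns = candidate sites) and a
list of problems; solves each with HiGHS via scipy.optimize.milp; writes a
JSON result map.

Formulation per problem (columns restricted to the sites that may open):
    min sum_c sum_h w[c,h] x[c,h]
    s.t. sum_h x[c,h] = 1                       for every demand point c
         linking: x[c,h] <= y[h]  (per_pair)    or
                  sum_c x[c,h] <= M y[h]  (big_m)
         sum_h y[h] = p
         y binary; pinned-open sites have y fixed to 1
         x continuous in [0,1]

x may be declared continuous without loss of exactness: for any binary y
an optimal x assigns each demand point wholly to its cheapest open site.
The caller re-derives assignments nearest-open anyway.
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, milp


def solve_problem(W, prob):
    cols = np.asarray(prob["columns"], dtype=int)  # 0-based, may open
    pinned = set(prob.get("pinned_open", []))
    p = int(prob["cardinality"])
    linking = prob.get("linking", "per_pair")
    m = W.shape[0]
    n = len(cols)
    if p > n:
        return {"status": "infeasible"}
    Wsub = W[:, cols]
    nx = m * n
    obj = np.concatenate([Wsub.ravel(), np.zeros(n)])

    cons = []
    rows = np.repeat(np.arange(m), n)
    a1 = sparse.csr_matrix((np.ones(nx), (rows, np.arange(nx))),
                           shape=(m, nx + n))
    cons.append(LinearConstraint(a1, 1, 1))
    if linking == "per_pair":
        r = np.arange(nx)
        a2 = sparse.csr_matrix(
            (np.concatenate([np.ones(nx), -np.ones(nx)]),
             (np.concatenate([r, r]),
              np.concatenate([np.arange(nx),
                              nx + np.tile(np.arange(n), m)]))),
            shape=(nx, nx + n))
        cons.append(LinearConstraint(a2, -np.inf, 0))
    elif linking == "big_m":
        big_m = float(prob.get("big_m") or m)
        a2 = sparse.csr_matrix(
            (np.concatenate([np.ones(nx), -big_m * np.ones(n)]),
             (np.concatenate([np.tile(np.arange(n), m), np.arange(n)]),
              np.concatenate([np.arange(nx), nx + np.arange(n)]))),
            shape=(n, nx + n))
        cons.append(LinearConstraint(a2, -np.inf, 0))
    else:
        raise ValueError("unknown linking: %s" % linking)
    ay = sparse.csr_matrix((np.ones(n), (np.zeros(n), nx + np.arange(n))),
                           shape=(1, nx + n))
    cons.append(LinearConstraint(ay, p, p))

    lb = np.zeros(nx + n)
    ub = np.ones(nx + n)
    for j, col in enumerate(cols):
        if col in pinned:
            lb[nx + j] = 1.0
    integrality = np.concatenate([np.zeros(nx), np.ones(n)])
    options = {"mip_rel_gap": float(prob.get("mip_gap", 1e-6)),
               "presolve": True}
    if prob.get("time_limit"):
        options["time_limit"] = float(prob["time_limit"])
    res = milp(obj, constraints=cons, integrality=integrality,
               bounds=Bounds(lb, ub), options=options)
    if res.status != 0 or res.x is None:
        status = "infeasible" if res.status == 2 else "failed"
        return {"status": status, "message": res.message}
    y = res.x[nx:]
    order = np.argsort(-y)[:p]          # p largest y, robust to 1-eps values
    open_cols = sorted(cols[j] for j in order)
    return {"status": "optimal",
            "open": [int(c) for c in open_cols],
            "objective": float(res.fun),
            "gap": float(getattr(res, "mip_gap", 0.0) or 0.0)}


def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    W = np.loadtxt(job["w_csv"], delimiter=",", ndmin=2)
    out = {}
    for prob in job["problems"]:
        out[prob["name"]] = solve_problem(W, prob)
    with open(job["out"], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1])
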