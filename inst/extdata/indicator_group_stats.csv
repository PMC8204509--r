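indicator,mean_noad,sd_noad,n_noad,mean_ad,sd_ad,n_ad,printed_d
TripDist,8.1,2.6,75,7.9,2.8,64,0.07
TotalDist,891.5,371.4,75,787.5,368.8,64,0.28
nTrips,113.7,40.4,75,103.3,41.9,64,0.25
Rg,67.0,98.8,75,44.0,63.5,64,0.27
S,3.97,0.5,75,3.84,0.5,64,0.26
nNightTrip,53.2,19.4,75,46.43,19.7,64,-0.35
nUniqDest,38.2,13.0,75,34.8,13.9,64,0.25
nHardBrake,0.027,0.04,75,0.022,0.02,64,0.15
nSuddenAcc,0.039,0.05,75,0.034,0.03,64,0.12
OverV,0.07,0.08,75,0.06,0.05,64,-0.15
UnderV,0.20,0.12,75,0.23,0.15,64,-0.22
avgV,8.03,1.87,75,8.04,1.83,64,-0.01
avgA,2.84,0.35,75,2.79,0.41,64,0.15
avgJ,1.46,0.16,75,1.39,0.20,64,0.39
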