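name,heavy_chain,light_chain,fv_charge,sharma_score,tomar_score,scm_score,visc_100,visc_100_sd,visc_100_extrapolated,visc_150,visc_150_sd,visc_150_extrapolated,conc_at_20cp,conc_at_20cp_sd
AB-001,AB-001_HC,AB-001_LC,-2.01,78.17,0.759,-2213,40.4,1.1,TRUE,439.7,127.8,TRUE,82.9,2.5
R1-002,E6Q_K94R,AB-001_LC,-1.07,76.87,0.778,-2008,29.3,0.9,FALSE,288.3,91.0,TRUE,90.1,3.5
R1-003,Q13K_K94R,AB-001_LC,-1.01,74.96,0.769,-1985,39.5,2.5,TRUE,522.9,255.9,TRUE,84.9,4.7
R1-004,A23R_K94R,AB-001_LC,-1.01,66.55,0.788,-1961,36.0,1.1,FALSE,310.4,94.4,TRUE,85.1,3.2
R1-005,D52aN_K94R,AB-001_LC,-1.04,77.92,0.73,-1838,26.0,1.5,FALSE,190.2,17.4,TRUE,95.9,3.0
R1-006,Q100bR_K94R,AB-001_LC,-1.01,71.16,0.653,-1941,40.8,1.1,FALSE,313.7,21.6,TRUE,81.7,2.0
R1-007,E6Q_Q13K_K94R,AB-001_LC,-0.07,77.86,0.777,-1988,35.9,5.4,FALSE,233.2,10.3,FALSE,89.6,3.7
R1-008,AB-001_HC,E3V,-1.07,73.93,0.529,-2085,30.7,1.0,FALSE,567.2,181.1,TRUE,90.8,3.0
R1-009,AB-001_HC,T18R,-1.01,59.05,0.507,-2180,29.8,0.8,FALSE,430.4,162.3,TRUE,90.8,5.1
R1-010,AB-001_HC,N53K,-1.01,64.64,0.602,-1898,15.9,0.5,FALSE,98.6,11.4,TRUE,106.9,5.1
R1-011,AB-001_HC,D96N,-1.04,67.85,0.607,-2035,56.8,2.5,FALSE,519.4,164.6,TRUE,77.0,2.2
R1-012,E6Q_Q13K_K94R,E3V,0.87,67.48,0.639,-1861,39.2,1.5,FALSE,471.0,145.0,TRUE,82.5,3.5
R1-013,E6Q_K94R,T18R,-0.07,55.84,0.614,-1972,29.7,1.6,FALSE,414.3,285.4,TRUE,90.9,7.3
R1-014,E6Q_Q13K_K94R,T18R,0.93,54.13,0.599,-1983,27.5,2.4,FALSE,414.7,116.6,TRUE,89.2,4.2
R1-015,E6Q_Q13K_K94R,D96N,0.9,61.92,0.602,-1817,41.3,1.8,FALSE,452.1,211.4,TRUE,82.6,2.4
R1-016,E6Q_Q13K_K94R,N53K,0.93,58.99,0.645,-1706,14.5,0.3,FALSE,73.1,0.6,FALSE,109.0,4.8
R1-017,Q13K_K94R,T18R,-0.01,54.41,0.594,-1949,42.6,2.8,TRUE,1534,1077,TRUE,85.7,4.5
R1-018,Q100bR_K94R,T18R,-0.01,51.83,0.559,-1914,33.2,0.6,FALSE,415.8,70.6,TRUE,87.6,2.7
R2-001,R2-001_HC,R2-001_LC,3.87,28.09,0.221,-1503,6.0,2.0,FALSE,37.3,3.3,FALSE,132.1,7.2
R2-004,R2-001_HC,Y49H,4.63,22.71,0.099,-1480,14.8,1.3,FALSE,54.4,2.0,FALSE,110.8,5.7
R2-005,R2-001_HC,Y49R,4.87,19.43,0.078,-1456,9.7,5.9,FALSE,36.7,10.8,FALSE,107.2,17.7
R2-006,R2-001_HC,S52K,4.87,20.74,0.072,-1470,4.0,1.2,FALSE,12.6,2.6,FALSE,163.4,21.7
R2-007,R2-001_HC,S65K,4.87,20.74,0.054,-1433,6.4,3.0,FALSE,21.1,6.5,FALSE,134.6,17.5
R2-008,R2-001_HC,S67K,4.87,20.74,0.062,-1460,6.5,2.7,FALSE,23.0,6.8,FALSE,148.6,16.5
R2-009,R2-001_HC,G68K,4.87,20.18,0.076,-1469,3.6,0.7,FALSE,19.3,3.7,FALSE,141.6,10.6
R2-010,Y97H,R2-001_LC,4.63,24.61,0.246,-1656,9.6,0.7,FALSE,35.1,1.6,FALSE,122.6,11.7
R2-011,Q100bK,R2-001_LC,4.87,23.79,0.209,-1500,13.1,2.2,FALSE,25.8,2.4,FALSE,131.3,11.8
R2-012,D52aK,R2-001_LC,5.85,20.9,0.226,-1273,12.3,3.3,FALSE,38.9,6.0,FALSE,133.1,5.7
R2-013,D52aN,R2-001_LC,4.85,24.77,0.244,-1357,7.1,1.4,FALSE,26.4,4.3,FALSE,133.2,21.6
R2-014,D53Q,R2-001_LC,4.85,24.68,0.17,-1378,12.5,0.8,FALSE,50.8,2.1,FALSE,121.4,5.0
R2-015,D61N,R2-001_LC,4.85,24.77,0.237,-1446,15.8,1.9,FALSE,83.2,3.2,FALSE,107.3,6.0
R2-016,D101N,R2-001_LC,4.85,24.77,0.231,-1416,14.1,1.2,FALSE,66.5,3.0,TRUE,111.2,5.0
R2-017,D101Y,R2-001_LC,4.85,26,0.239,-1564,8.8,0.8,FALSE,83.5,2.8,FALSE,115.4,5.4
R2-018,R2-001_HC,D26N,4.85,22.34,0.06,-1346,3.4,0.9,FALSE,19.9,7.1,FALSE,127.4,24.2
R2-019,R2-001_HC,D50L,4.85,24.22,0.079,-1503,23.2,6.2,FALSE,59.5,6.6,FALSE,91.3,15.0
R2-020,R2-001_HC,D51N,4.85,22.34,0.05,-1363,4.1,0.1,FALSE,10.0,0.2,FALSE,182.4,2.0
R2-021,R2-001_HC,D96K,5.85,16.96,-0.104,-1197,24.2,4.8,FALSE,118.9,10.9,FALSE,100.2,3.5
R2-022,R2-001_HC,D96N,4.85,22.34,0.072,-1311,25.2,1.6,FALSE,134.7,2.6,FALSE,98.5,2.5
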