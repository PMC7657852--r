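region,iteration,pressure,mean_MPa,sd_MPa
shell_wall,1,1,21.91,15.7
shell_wall,1,2,44.75,32.2
shell_wall,1,3,66.18,47.3
shell_wall,2,1,18.73,14.1
shell_wall,2,2,39.88,29.7
shell_wall,2,3,58.47,43.3
shell_wall,3,1,17.75,12.7
shell_wall,3,2,36.95,25.6
shell_wall,3,3,55.70,38.3
septum,1,1,6.32,7.33
septum,1,2,10.33,13.2
septum,1,3,15.88,20.73
septum,2,1,11.03,9.38
septum,2,2,20.34,19.1
septum,2,3,32.40,19.10
septum,3,1,17.10,9.81
septum,3,2,29.45,18.4
septum,3,3,47.40,27.82
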