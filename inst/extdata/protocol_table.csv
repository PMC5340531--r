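ion_class,protocol,V0,V1,V2,V3,dV,T1,T2,T3,T4,T5,T6,T7,T8,T9,TA,TB
Kv,activation,-80,-80,70,NA,10,100,500,100,NA,NA,NA,NA,NA,NA,100,700
Nav,activation,-80,-80,70,NA,10,20,50,30,NA,NA,NA,NA,NA,NA,18,100
Cav,activation,-80,-80,70,NA,10,100,500,100,NA,NA,NA,NA,NA,NA,98,700
KCa,activation,-80,-80,70,NA,10,100,500,100,NA,NA,NA,NA,NA,NA,95,605
Ih,activation,-40,-150,0,NA,10,100,2000,100,NA,NA,NA,NA,NA,NA,95,2105
Kv,inactivation,-80,-40,70,30,10,100,1500,50,100,NA,NA,NA,NA,NA,1600,1700
Nav,inactivation,-80,-40,70,30,10,100,1500,50,100,NA,NA,NA,NA,NA,1580,1750
Cav,inactivation,-80,-40,70,30,10,100,1500,50,100,NA,NA,NA,NA,NA,1580,1750
KCa,inactivation,-80,-40,70,30,10,100,1500,50,100,NA,NA,NA,NA,NA,1595,1700
Ih,inactivation,-40,-150,-40,-120,10,100,1000,300,100,NA,NA,NA,NA,NA,1095,1405
Kv,deactivation,-80,70,-100,40,10,100,300,200,100,NA,NA,NA,NA,NA,400,600
Nav,deactivation,-80,70,-100,40,10,20,10,30,20,NA,NA,NA,NA,NA,29,80
Cav,deactivation,-80,70,-100,40,10,100,300,200,100,NA,NA,NA,NA,NA,380,700
KCa,deactivation,-80,70,-100,40,10,100,300,200,100,NA,NA,NA,NA,NA,395,605
Ih,deactivation,-40,-140,-110,0,10,100,1500,500,400,NA,NA,NA,NA,NA,1595,2105
Kv,ramp,-80,70,NA,NA,NA,100,800,400,400,400,200,400,100,100,100,2800
Nav,ramp,-80,70,NA,NA,NA,100,800,400,400,400,200,400,100,100,98,2800
Cav,ramp,-80,70,NA,NA,NA,100,800,400,400,400,200,400,100,100,98,2800
KCa,ramp,-80,70,NA,NA,NA,100,800,400,400,400,200,400,100,100,100,2800
Ih,ramp,-80,70,NA,NA,NA,100,800,400,400,400,200,400,100,100,100,2800
Kv,action_potential,NA,NA,NA,NA,NA,1800,NA,NA,NA,NA,NA,NA,NA,NA,100,1800
Nav,action_potential,NA,NA,NA,NA,NA,1800,NA,NA,NA,NA,NA,NA,NA,NA,98,1800
Cav,action_potential,NA,NA,NA,NA,NA,1800,NA,NA,NA,NA,NA,NA,NA,NA,98,1800
KCa,action_potential,NA,NA,NA,NA,NA,1800,NA,NA,NA,NA,NA,NA,NA,NA,95,1655
Ih,action_potential,NA,NA,NA,NA,NA,1800,NA,NA,NA,NA,NA,NA,NA,NA,95,1655
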